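DEFAULT_CALLERS <- c("freec", "cnaseq", "delly", "abyss")
CNV_TYPES <- c("gain", "loss", "inv", "trans")

#' Simulate multi-caller CNV/SV call sets for a trio
#'
#' Plants `n_cnv` true copy-number/structural events per trio. Each event is
#' emitted by a random subset of callers (larger subsets are rarer,
#' mimicking the low cross-algorithm concordance of read-depth, split-read
#' and assembly callers) with independent per-caller breakpoint jitter up to
#' `boundary_jitter_bp`. Inherited events appear in one parent's call sets
#' with the same caller subset; de novo events appear in the child only.
#' Caller-private false positives are added per caller per sample at a
#' Poisson rate of `cnv_fp_rate`. One maternally inherited balanced
#' translocation is planted as a paired-breakend record.
#'
#' Coordinates are 0-based half-open throughout.
#'
#' @param config A [sim_config()].
#' @return A list with `calls` (one data frame of all calls: `chrom`,
#'   `start`, `end`, `type`, `caller`, `sample`, `support_reads`, and
#'   `chrom2`/`pos2` for translocation mates), and `truth` (planted events
#'   with inheritance and emitting callers, plus false-positive counts).
#' @export
simulate_cnv_callsets <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "cnv"))
  callers <- if (config$n_callers <= length(DEFAULT_CALLERS))
    DEFAULT_CALLERS[seq_len(config$n_callers)]
  else c(DEFAULT_CALLERS, paste0("caller", seq_len(config$n_callers - 4) + 4))
  autos <- setdiff(names(config$chrom_lengths), "chrX")
  jit <- config$boundary_jitter_bp

  # planted events and false positives are kept mutually disjoint so that
  # truth labels (de novo vs inherited, true vs false call) stay unambiguous
  placed <- list()
  auto_len <- sum(config$chrom_lengths[autos])
  rand_interval <- function(min_len = 1e3,
                            max_len = min(2e5, round(0.015 * auto_len))) {
    for (try in 1:500) {
      chrom <- sample(autos, 1L)
      len <- round(10^runif(1, log10(min_len), log10(max_len)))
      len <- min(len, config$chrom_lengths[[chrom]] - 2L)
      start <- sample.int(config$chrom_lengths[[chrom]] - len, 1L) - 1L
      iv <- list(chrom = chrom, start = start, end = start + len)
      clash <- any(vapply(placed, function(p)
        p$chrom == iv$chrom && p$start < iv$end && iv$start < p$end,
        logical(1)))
      if (!clash) {
        placed[[length(placed) + 1L]] <<- iv
        return(iv)
      }
    }
    stop("could not place a disjoint CNV interval; reduce n_cnv or cnv_fp_rate",
         call. = FALSE)
  }

  n <- config$n_cnv
  truth <- vector("list", n)
  calls <- list()
  subset_sizes <- sample(seq_along(callers), n, replace = TRUE,
                         prob = c(0.45, 0.3, 0.15, 0.1)[seq_along(callers)] /
                           sum(c(0.45, 0.3, 0.15, 0.1)[seq_along(callers)]))
  inh <- sample(c("de_novo", "maternal", "paternal"), n, replace = TRUE,
                prob = c(0.25, 0.375, 0.375))

  emit <- function(ev, who, caller) {
    s <- max(0L, ev$start + sample(-jit:jit, 1L))
    e <- ev$end + sample(-jit:jit, 1L)
    if (e <= s) e <- s + 1L
    data.frame(chrom = ev$chrom, start = s, end = e, type = ev$type,
               caller = caller, sample = who,
               support_reads = 5L + rpois(1L, 20),
               chrom2 = NA_character_, pos2 = NA_integer_,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    iv <- rand_interval()
    ev <- list(event_id = sprintf("cnv%03d", i), chrom = iv$chrom,
               start = iv$start, end = iv$end,
               type = sample(c("gain", "loss", "inv"), 1L,
                             prob = c(0.4, 0.45, 0.15)),
               inheritance = inh[i],
               callers = sort(sample(callers, subset_sizes[i])))
    truth[[i]] <- ev
    samples <- switch(ev$inheritance,
                      de_novo = "child",
                      maternal = c("child", "mother"),
                      paternal = c("child", "father"))
    for (who in samples)
      for (cl in ev$callers) calls[[length(calls) + 1L]] <- emit(ev, who, cl)
  }

  # one maternally inherited balanced translocation (paired breakends),
  # called by the split-read and assembly callers only
  tr_callers <- intersect(c("delly", "abyss"), callers)
  if (length(tr_callers) == 0L) tr_callers <- callers[1]
  b1 <- rand_interval(); b2 <- rand_interval()
  while (b2$chrom == b1$chrom) b2 <- rand_interval()
  tr <- list(event_id = "trans001", chrom = b1$chrom, start = b1$start,
             end = b1$start + 1L, type = "trans", inheritance = "maternal",
             callers = tr_callers, chrom2 = b2$chrom, pos2 = b2$start)
  for (who in c("child", "mother"))
    for (cl in tr_callers) {
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = tr$chrom, start = tr$start, end = tr$start + 1L,
        type = "trans", caller = cl, sample = who,
        support_reads = 5L + rpois(1L, 10),
        chrom2 = tr$chrom2, pos2 = tr$pos2, stringsAsFactors = FALSE)
    }

  # caller-private false positives
  fp_counts <- list()
  for (who in c("child", "mother", "father"))
    for (cl in callers) {
      k <- rpois(1L, config$cnv_fp_rate)
      fp_counts[[paste(who, cl, sep = ".")]] <- k
      for (j in seq_len(k)) {
        iv <- rand_interval()
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = iv$chrom, start = iv$start, end = iv$end,
          type = sample(c("gain", "loss", "inv"), 1L),
          caller = cl, sample = who, support_reads = 1L + rpois(1L, 4),
          chrom2 = NA_character_, pos2 = NA_integer_, stringsAsFactors = FALSE)
      }
    }

  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  truth_df <- do.call(rbind, lapply(truth, function(ev)
    data.frame(event_id = ev$event_id, chrom = ev$chrom, start = ev$start,
               end = ev$end, type = ev$type, inheritance = ev$inheritance,
               callers = paste(ev$callers, collapse = ","),
               n_callers = length(ev$callers), stringsAsFactors = FALSE)))
  list(calls = calls,
       truth = list(events = truth_df, translocation = tr,
                    fp_counts = fp_counts, callers = callers),
       config = config)
}

#' Simulate assembly-derived small indel candidates
#'
#' Emulates the candidate indel list produced by de novo genome assembly:
#' many raw events of size 1-100 bp, a minority with strong read support and
#' a protein-coding consequence.
#'
#' @param config A [sim_config()].
#' @param n_indels Number of raw candidate indels.
#' @return List with `indels` (data frame: interval, `size`, inserted or
#'   deleted `seq`, `spanning_reads`, `coding_change`) and `truth` (count of
#'   events passing the support-and-coding filter).
#' @export
simulate_assembly_indels <- function(config, n_indels = 700) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "indels"))
  autos <- setdiff(names(config$chrom_lengths), "chrX")
  chrom <- sample(autos, n_indels, replace = TRUE)
  size <- pmax(1L, pmin(100L, 1L + rpois(n_indels, 4)))
  start <- vapply(chrom, function(cc)
    sample.int(config$chrom_lengths[[cc]] - 101L, 1L) - 1L, integer(1))
  indels <- data.frame(
    chrom = chrom, start = start, end = start + size, size = size,
    op = sample(c("ins", "del"), n_indels, replace = TRUE),
    spanning_reads = rpois(n_indels, 4),
    coding_change = runif(n_indels) < 0.15,
    stringsAsFactors = FALSE)
  list(indels = indels,
       truth = list(n_pass = sum(indels$spanning_reads >= 7 &
                                   indels$coding_change)),
       config = config)
}
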