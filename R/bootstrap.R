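#' Gene-set bootstrap null for candidate-gene burden
#'
#' Tests whether the observed per-gene damaging-variant burden of a
#' candidate gene set could arise by random gene sampling: each replicate
#' draws `set_size` genes uniformly without replacement from the gene
#' universe and records the mean (and median) per-gene carrier count in the
#' case cohort. The observed statistic is computed on the candidate set and
#' compared against the null sample with the add-one empirical estimator
#' `p = (1 + #[null >= observed]) / (1 + reps)`, which avoids p = 0
#' artifacts at finite replicate counts.
#'
#' @param case A [cohort_table()] (the positive-control cohort).
#' @param candidate_genes Character vector of candidate gene ids.
#' @param universe Gene universe to resample from.
#' @param reps Number of bootstrap replicates (default 1000).
#' @param set_size Genes drawn per replicate (default 6, the candidate-set
#'   size of the motivating design).
#' @param seed Integer seed.
#' @return List with one `bootstrap_result` per statistic (`mean`,
#'   `median`): `observed`, `null` (replicate values), `p`, `reps`, `seed`.
#' @export
bootstrap_gene_sets <- function(case, candidate_genes, universe,
                                reps = 1000, set_size = 6, seed = 1L) {
  stopifnot(inherits(case, "cohort_table"))
  if (set_size > length(universe))
    stop("set_size (", set_size, ") exceeds gene universe size (",
         length(universe), ")", call. = FALSE)
  if (!all(candidate_genes %in% universe))
    stop("candidate genes outside the universe: ",
         paste(setdiff(candidate_genes, universe), collapse = ", "),
         call. = FALSE)
  # resample over the sorted universe so the null (and hence the empirical
  # p) is invariant to the ordering in which the universe is supplied
  universe <- sort(unique(universe))
  u <- unique(case$carriers[c("individual", "gene")])
  counts <- table(factor(u$gene, levels = universe))
  burden <- as.numeric(counts)
  names(burden) <- universe

  set.seed(derive_seed(seed, "bootstrap"))
  draws <- replicate(reps, sample.int(length(universe), set_size))
  null_mean <- colMeans(matrix(burden[draws], nrow = set_size))
  null_median <- apply(matrix(burden[draws], nrow = set_size), 2L, stats::median)

  result <- function(stat, observed, null) {
    list(statistic = stat, observed = observed, null = null,
         p = (1 + sum(null >= observed)) / (1 + reps),
         reps = reps, set_size = set_size, seed = seed)
  }
  obs <- burden[candidate_genes]
  list(mean = result("mean", mean(obs), null_mean),
       median = result("median", stats::median(obs), null_median))
}
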