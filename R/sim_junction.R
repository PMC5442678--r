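# 0-based half-open substring of a chromosome in a DNAStringSet
ref_sub <- function(reference, chrom, start0, end0) {
  stopifnot(start0 >= 0, end0 >= start0)
  if (end0 == start0) return("")
  as.character(Biostrings::subseq(reference[[chrom]], start0 + 1L, end0))
}

#' Simulate a breakpoint-junction contig with planted microhomology and inserts
#'
#' Models the sequence architecture of a large-deletion breakpoint junction:
#' the contig reads from the proximal (left) reference flank, through zero or
#' more templated insertions copied from other chromosomes, into the distal
#' (right) reference flank. A microhomology of exactly
#' `config$microhomology_len` bases is planted by overwriting the reference
#' immediately upstream of the distal resumption point with the terminal
#' bases of the segment that precedes it in the contig, so that the shared
#' sequence is present at both donor junction ends (as in
#' microhomology-mediated repair signatures).
#'
#' @param config A [sim_config()]; `microhomology_len` and `insert_len`
#'   control the plant.
#' @param flank_len Length (bp) of each reference flank in the contig.
#' @return A list with `contig` (character), `reference` (the
#'   [Biostrings::DNAStringSet] after the homology plant), `junction` (a
#'   junction model: `contig`, `left` segment `(chrom, start0, end0)`,
#'   `right` segment `(chrom, start0, end0)`, 0-based half-open), and
#'   `truth` (planted microhomology string and insert origins).
#' @export
simulate_junction <- function(config, flank_len = 150L) {
  validate_sim_config(config)
  mh <- config$microhomology_len
  ins_len <- config$insert_len[config$insert_len > 0L]
  if (flank_len < mh)
    stop("flank_len (", flank_len, ") shorter than microhomology_len (",
         mh, ")", call. = FALSE)
  if (length(ins_len) && mh > 0 && utils::tail(ins_len, 1) < mh)
    stop("last insert shorter than microhomology_len", call. = FALSE)
  reference <- simulate_reference(config)
  set.seed(derive_seed(config$seed, "junction"))

  chrom <- names(config$chrom_lengths)[1]
  clen <- config$chrom_lengths[[chrom]]
  del_len <- round(min(0.17 * clen, clen - 4 * flank_len - 10))
  del_start <- sample.int(clen - del_len - 2L * flank_len, 1L) + flank_len
  del_end <- del_start + del_len  # resumption point, 0-based

  donors <- setdiff(names(config$chrom_lengths), c(chrom, "chrX"))
  inserts <- lapply(ins_len, function(L) {
    oc <- sample(donors, 1L)
    os <- sample.int(config$chrom_lengths[[oc]] - L - 1L, 1L)
    list(chrom = oc, start0 = os, end0 = os + L,
         seq = ref_sub(reference, oc, os, os + L))
  })

  # keep insert boundaries crisp: the reference base just past each
  # insert's origin must differ from the next base in the contig, so an
  # exact-match origin search cannot overrun the planted boundary
  if (length(inserts) > 1L) {
    for (i in seq_len(length(inserts) - 1L)) {
      nxt <- substring(inserts[[i + 1L]]$seq, 1L, 1L)
      o <- inserts[[i]]
      after <- ref_sub(reference, o$chrom, o$end0, o$end0 + 1L)
      if (identical(after, nxt)) {
        reference[[o$chrom]] <- Biostrings::replaceAt(
          reference[[o$chrom]], IRanges::IRanges(o$end0 + 1L, o$end0 + 1L),
          Biostrings::DNAString(sample(setdiff(c("A", "C", "G", "T"), nxt), 1L)))
      }
    }
  }

  left_seq <- ref_sub(reference, chrom, del_start - flank_len, del_start)
  pre_seg <- if (length(inserts)) utils::tail(inserts, 1)[[1]]$seq else left_seq
  mh_seq <- if (mh > 0) substring(pre_seg, nchar(pre_seg) - mh + 1L) else ""
  if (mh > 0) {
    # plant: the distal donor carries the same bases just before resumption
    reference[[chrom]] <- Biostrings::replaceAt(
      reference[[chrom]],
      IRanges::IRanges(del_end - mh + 1L, del_end),
      Biostrings::DNAString(mh_seq))
  }
  # ensure the homology cannot extend by chance one base further upstream
  donor_prev <- if (length(inserts)) {
    li <- utils::tail(inserts, 1)[[1]]
    ref_sub(reference, li$chrom, li$end0 - mh - 1L, li$end0 - mh)
  } else ref_sub(reference, chrom, del_start - mh - 1L, del_start - mh)
  right_prev <- ref_sub(reference, chrom, del_end - mh - 1L, del_end - mh)
  if (identical(donor_prev, right_prev)) {
    reference[[chrom]] <- Biostrings::replaceAt(
      reference[[chrom]], IRanges::IRanges(del_end - mh, del_end - mh),
      Biostrings::DNAString(sample(setdiff(c("A", "C", "G", "T"), donor_prev), 1L)))
  }
  right_seq <- ref_sub(reference, chrom, del_end, del_end + flank_len)
  contig <- paste0(left_seq, paste(vapply(inserts, `[[`, "", "seq"),
                                   collapse = ""), right_seq)

  junction <- list(
    contig = contig,
    left = list(chrom = chrom, start0 = del_start - flank_len,
                end0 = del_start),
    right = list(chrom = chrom, start0 = del_end, end0 = del_end + flank_len))
  truth <- list(
    microhomology = mh_seq,
    deletion = list(chrom = chrom, start0 = del_start, end0 = del_end),
    inserts = lapply(inserts, function(x) x[c("chrom", "start0", "end0", "seq")]))
  list(contig = contig, reference = reference, junction = junction,
       truth = truth, config = config)
}
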