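# longest common suffix of two strings, in bases
longest_common_suffix <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0L)
  av <- rev(strsplit(a, "", fixed = TRUE)[[1]])
  bv <- rev(strsplit(b, "", fixed = TRUE)[[1]])
  k <- min(length(av), length(bv))
  eq <- av[seq_len(k)] == bv[seq_len(k)]
  if (!eq[1]) return(0L)
  which.min(c(eq, FALSE)) - 1L
}

#' Detect junction microhomology between two donor ends
#'
#' The microhomology of a rearrangement junction is the maximal exact
#' sequence present at both donor junction ends: the bases terminating the
#' segment that precedes the junction, and the bases immediately upstream
#' of the resumption point in the distal donor. Operationally this is the
#' longest common suffix of the two donor-end sequences; an empty string
#' indicates a blunt joint.
#'
#' @param left_end_seq Reference sequence ending at the proximal donor's
#'   junction end (the last segment copied into the contig before the
#'   junction).
#' @param right_end_seq Reference sequence ending immediately before the
#'   distal donor's resumption point.
#' @param search_window Number of bases to examine (default 50); both input
#'   sequences must be at least this long.
#' @return List with `seq` (the microhomology string, possibly `""`) and
#'   `length`.
#' @export
detect_microhomology <- function(left_end_seq, right_end_seq,
                                 search_window = 50L) {
  if (nchar(left_end_seq) < search_window || nchar(right_end_seq) < search_window)
    stop("donor flank shorter than the requested search window (",
         search_window, " bp)", call. = FALSE)
  a <- substring(left_end_seq, nchar(left_end_seq) - search_window + 1L)
  b <- substring(right_end_seq, nchar(right_end_seq) - search_window + 1L)
  len <- longest_common_suffix(a, b)
  list(seq = if (len > 0) substring(a, nchar(a) - len + 1L) else "",
       length = len)
}

#' Extract the two donor-end flank sequences of a junction
#'
#' @param junction Junction model (`left`/`right` segments with `chrom`,
#'   `start0`, `end0`), see [simulate_junction()].
#' @param reference [Biostrings::DNAStringSet] of donor chromosomes.
#' @param window Flank length to extract (default 50).
#' @param last_segment Optional override for the segment preceding the
#'   junction (a list with `chrom`, `end0`), e.g. the final templated
#'   insert; defaults to the junction's left segment.
#' @return List with `left_end_seq` and `right_end_seq`.
#' @export
junction_donor_flanks <- function(junction, reference, window = 50L,
                                  last_segment = NULL) {
  seg <- if (is.null(last_segment)) {
    list(chrom = junction$left$chrom, end0 = junction$left$end0)
  } else last_segment
  list(
    left_end_seq = ref_sub(reference, seg$chrom, seg$end0 - window, seg$end0),
    right_end_seq = ref_sub(reference, junction$right$chrom,
                            junction$right$start0 - window,
                            junction$right$start0))
}

# greedy longest-prefix decomposition of an inserted sequence into
# reference-templated pieces: seed with a min_match-length exact hit, then
# extend each hit as far as the reference keeps matching; the longest
# extension wins (first hit on ties)
decompose_insert <- function(middle, reference, min_match = 15L) {
  pieces <- list()
  while (nchar(middle) > 0L) {
    if (nchar(middle) < min_match) {
      pieces[[length(pieces) + 1L]] <- list(seq = middle, chrom = NA_character_,
                                            start0 = NA_integer_,
                                            end0 = NA_integer_, n_hits = 0L)
      break
    }
    probe <- substring(middle, 1L, min_match)
    best <- NULL
    n_hits_total <- 0L
    for (cc in names(reference)) {
      hits <- Biostrings::matchPattern(probe, reference[[cc]])
      n_hits_total <- n_hits_total + length(hits)
      for (h in seq_len(length(hits))) {
        s0 <- Biostrings::start(hits)[h] - 1L
        max_ext <- min(nchar(middle), length(reference[[cc]]) - s0)
        ext <- min_match
        while (ext < max_ext &&
               substring(middle, ext + 1L, ext + 1L) ==
               ref_sub(reference, cc, s0 + ext, s0 + ext + 1L)) {
          ext <- ext + 1L
        }
        if (is.null(best) || ext > best$len)
          best <- list(len = ext, chrom = cc, start0 = s0)
      }
    }
    if (is.null(best)) {
      pieces[[length(pieces) + 1L]] <- list(seq = middle, chrom = NA_character_,
                                            start0 = NA_integer_,
                                            end0 = NA_integer_, n_hits = 0L)
      break
    }
    pieces[[length(pieces) + 1L]] <- list(
      seq = substring(middle, 1L, best$len), chrom = best$chrom,
      start0 = best$start0, end0 = best$start0 + best$len,
      n_hits = n_hits_total)
    middle <- substring(middle, best$len + 1L)
  }
  pieces
}

#' Characterize a breakpoint-junction contig
#'
#' Partitions the contig into proximal flank, inserted segments and distal
#' flank using the junction model's segment coordinates, verifies both
#' flanks against the reference, searches each inserted segment against the
#' whole reference for its templated origin (exact match; all hit loci
#' reported, first used), and measures the junction microhomology at the
#' distal joint. The junction signature is:
#'
#' * `blunt`: no insert, zero-length microhomology;
#' * `microhomology`: no insert, positive microhomology;
#' * `templated-insertion`: exactly one inserted segment;
#' * `complex`: two or more inserted segments, or inserts from two or more
#'   chromosomes;
#' * `unresolved`: a contig flank does not match the reference at the
#'   declared segment (diagnostics attached).
#'
#' @param junction Junction model (see [simulate_junction()]).
#' @param reference [Biostrings::DNAStringSet].
#' @param min_insert_match Minimum exact-match length for origin assignment
#'   (default 15 bp).
#' @param mh_window Microhomology search window (default 50 bp).
#' @return List: `signature`, `microhomology` (`seq`, `length`), `inserts`
#'   (list of `seq`, `chrom`, `start0`, `end0`, `n_hits`), `segments`, and
#'   `diagnostics`.
#' @export
classify_junction <- function(junction, reference, min_insert_match = 15L,
                              mh_window = 50L) {
  contig <- junction$contig
  fl <- junction$left$end0 - junction$left$start0
  fr <- junction$right$end0 - junction$right$start0
  n <- nchar(contig)
  if (fl + fr > n)
    return(list(signature = "unresolved", microhomology = NULL,
                inserts = list(), segments = NULL,
                diagnostics = "declared segments longer than contig"))
  left_obs <- substring(contig, 1L, fl)
  right_obs <- substring(contig, n - fr + 1L)
  left_ref <- ref_sub(reference, junction$left$chrom,
                      junction$left$start0, junction$left$end0)
  right_ref <- ref_sub(reference, junction$right$chrom,
                       junction$right$start0, junction$right$end0)
  if (!identical(left_obs, left_ref) || !identical(right_obs, right_ref))
    return(list(signature = "unresolved", microhomology = NULL,
                inserts = list(), segments = NULL,
                diagnostics = "contig flank does not match reference segment"))

  middle <- substring(contig, fl + 1L, n - fr)
  inserts <- if (nchar(middle) > 0L) {
    decompose_insert(middle, reference, min_insert_match)
  } else list()

  last_seg <- if (length(inserts)) {
    li <- inserts[[length(inserts)]]
    if (!is.na(li$chrom)) list(chrom = li$chrom, end0 = li$end0) else NULL
  } else NULL
  flanks <- junction_donor_flanks(junction, reference, window = mh_window,
                                  last_segment = last_seg)
  mh <- detect_microhomology(flanks$left_end_seq, flanks$right_end_seq,
                             search_window = mh_window)

  origin_chroms <- unique(stats::na.omit(
    vapply(inserts, function(x) x$chrom, character(1))))
  signature <- if (length(inserts) == 0L) {
    if (mh$length > 0L) "microhomology" else "blunt"
  } else if (length(inserts) >= 2L || length(origin_chroms) >= 2L) {
    "complex"
  } else "templated-insertion"

  list(signature = signature, microhomology = mh, inserts = inserts,
       segments = list(left = junction$left, right = junction$right),
       diagnostics = NULL)
}
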