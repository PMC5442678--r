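#' Parse BED-like CNV/SV call-set files
#'
#' Reads per-caller call tables (`chrom`, `start`, `end`, `type`, `caller`,
#' `sample`, `support_reads`, optional `chrom2`/`pos2` for translocation
#' mates) and normalizes coordinates to 0-based half-open. Lines with an
#' unknown type token or a non-positive interval are rejected with a
#' warning; the rejected count is attached as attribute `n_skipped`.
#'
#' @param files Character vector of file paths.
#' @param dialect `"bed0"` for 0-based half-open input (default) or
#'   `"onebased"` for 1-based inclusive (start is decremented on ingest).
#' @param caller_map Optional named vector renaming caller ids.
#' @return Combined call data frame with attribute `n_skipped`.
#' @export
parse_callsets <- function(files, dialect = c("bed0", "onebased"),
                           caller_map = NULL) {
  dialect <- match.arg(dialect)
  parts <- lapply(files, function(f)
    read_tsv(f, colClasses = list(chrom = "character")))
  calls <- do.call(rbind, parts)
  if (is.null(calls) || nrow(calls) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      type = character(), caller = character(),
                      sample = character(), support_reads = integer(),
                      chrom2 = character(), pos2 = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  if (!"chrom2" %in% names(calls)) calls$chrom2 <- NA_character_
  if (!"pos2" %in% names(calls)) calls$pos2 <- NA_integer_
  if (dialect == "onebased") {
    calls$start <- calls$start - 1L
    calls$pos2 <- ifelse(is.na(calls$pos2), NA_integer_, calls$pos2 - 1L)
  }
  bad_type <- !(calls$type %in% CNV_TYPES)
  bad_iv <- !(calls$end > calls$start) | is.na(calls$start) | is.na(calls$end)
  bad <- bad_type | bad_iv
  if (any(bad))
    warning(sum(bad), " malformed call line(s) skipped (",
            sum(bad_type), " unknown type, ", sum(bad_iv & !bad_type),
            " invalid interval)")
  calls <- calls[!bad, , drop = FALSE]
  if (!is.null(caller_map)) {
    hit <- calls$caller %in% names(caller_map)
    calls$caller[hit] <- unname(caller_map[calls$caller[hit]])
  }
  rownames(calls) <- NULL
  attr(calls, "n_skipped") <- sum(bad)
  calls
}

#' Write CNV calls as per-sample-per-caller BED-like TSV files
#'
#' @param calls Call data frame (as from [simulate_cnv_callsets()]).
#' @param dir Output directory.
#' @param dialect Coordinate dialect to emit (see [parse_callsets()]).
#' @return Character vector of file paths written.
#' @export
write_cnv_calls <- function(calls, dir, dialect = c("bed0", "onebased")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- calls
  if (dialect == "onebased") {
    out$start <- out$start + 1L
    out$pos2 <- ifelse(is.na(out$pos2), NA_integer_, out$pos2 + 1L)
  }
  groups <- split(out, paste(out$sample, out$caller, sep = "."))
  paths <- vapply(names(groups), function(g) {
    p <- file.path(dir, paste0(g, ".cnv.tsv"))
    write_tsv(groups[[g]], p)
    p
  }, character(1))
  unname(paths)
}

#' Reciprocal overlap between two genomic intervals
#'
#' `min(overlap / len_a, overlap / len_b)`; 0 for different chromosomes or
#' disjoint intervals. Symmetric by construction. Coordinates are 0-based
#' half-open.
#'
#' @param a,b Lists or one-row data frames with `chrom`, `start`, `end`.
#' @return Fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(0)
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}

#' Multi-caller consensus by single-linkage reciprocal overlap
#'
#' Same-type interval calls from one sample form a consensus cluster when
#' linked (transitively) by pairwise reciprocal overlap at or above
#' `ro_threshold`. Gains never merge with losses; inversions only match
#' inversions. Translocation calls cluster when both breakends lie within
#' `trans_window` bp of another call's breakends. A consensus is
#' high-confidence when two or more distinct callers support it.
#'
#' @param calls Call data frame for a single sample.
#' @param ro_threshold Reciprocal-overlap threshold (default 0.5).
#' @param trans_window Breakend matching window in bp (default 1000).
#' @return Consensus data frame: `consensus_id`, `chrom`, `start`, `end`
#'   (merged span), `type`, `n_callers`, `callers`, `n_calls`,
#'   `high_confidence`, plus a `members` list-column of member row indices.
#' @export
build_consensus <- function(calls, ro_threshold = 0.5, trans_window = 1000) {
  if (length(unique(calls$sample)) > 1L)
    stop("build_consensus expects calls from a single sample", call. = FALSE)
  n <- nrow(calls)
  if (n == 0L)
    return(data.frame(consensus_id = character(), chrom = character(),
                      start = integer(), end = integer(), type = character(),
                      n_callers = integer(), callers = character(),
                      n_calls = integer(), high_confidence = logical(),
                      stringsAsFactors = FALSE))
  linked <- function(i, j) {
    if (calls$type[i] != calls$type[j]) return(FALSE)
    if (calls$type[i] == "trans") {
      same1 <- calls$chrom[i] == calls$chrom[j] &&
        abs(calls$start[i] - calls$start[j]) <= trans_window
      same2 <- identical(calls$chrom2[i], calls$chrom2[j]) &&
        !is.na(calls$pos2[i]) && !is.na(calls$pos2[j]) &&
        abs(calls$pos2[i] - calls$pos2[j]) <= trans_window
      return(same1 && same2)
    }
    reciprocal_overlap(calls[i, ], calls[j, ]) >= ro_threshold
  }
  edges <- list()
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      if (linked(i, j)) edges[[length(edges) + 1L]] <- c(i, j)
  memb <- if (length(edges)) {
    g <- igraph::graph_from_data_frame(
      do.call(rbind, edges), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    igraph::components(g)$membership[as.character(seq_len(n))]
  } else seq_len(n)
  clusters <- split(seq_len(n), memb)
  out <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    idx <- clusters[[k]]
    callers <- sort(unique(calls$caller[idx]))
    data.frame(consensus_id = sprintf("cons%03d", k),
               chrom = calls$chrom[idx[1]],
               start = min(calls$start[idx]), end = max(calls$end[idx]),
               type = calls$type[idx[1]],
               n_callers = length(callers),
               callers = paste(callers, collapse = ","),
               n_calls = length(idx),
               high_confidence = length(callers) >= 2L,
               stringsAsFactors = FALSE)
  }))
  out$members <- unname(clusters)
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  out$consensus_id <- sprintf("cons%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Label consensus CNVs by inheritance against parental call sets
#'
#' A child consensus call is `de_novo` when no same-type parental call of
#' either parent reaches `ro_threshold` reciprocal overlap with it
#' (breakend-window matching for translocations); otherwise it is labelled
#' by the matching parent, or `ambiguous` when both parents match.
#'
#' @param consensus Child consensus table from [build_consensus()].
#' @param mother_calls,father_calls Parental call data frames.
#' @param ro_threshold,trans_window Matching parameters, as in
#'   [build_consensus()].
#' @return `consensus` with an added `inheritance` column.
#' @export
classify_inheritance <- function(consensus, mother_calls, father_calls,
                                 ro_threshold = 0.5, trans_window = 1000) {
  matches <- function(cons_row, calls) {
    if (nrow(calls) == 0L) return(FALSE)
    for (j in seq_len(nrow(calls))) {
      if (calls$type[j] != cons_row$type) next
      if (cons_row$type == "trans") {
        if (calls$chrom[j] == cons_row$chrom &&
            abs(calls$start[j] - cons_row$start) <= trans_window)
          return(TRUE)
      } else if (reciprocal_overlap(cons_row, calls[j, ]) >= ro_threshold) {
        return(TRUE)
      }
    }
    FALSE
  }
  consensus$inheritance <- vapply(seq_len(nrow(consensus)), function(i) {
    row <- consensus[i, ]
    in_m <- matches(row, mother_calls)
    in_f <- matches(row, father_calls)
    if (in_m && in_f) "ambiguous"
    else if (in_m) "maternal"
    else if (in_f) "paternal"
    else "de_novo"
  }, character(1))
  consensus
}

#' Interval length in base pairs or kilobases
#'
#' `end - start`, the span of a 0-based half-open interval; this convention
#' also reproduces printed spans of 1-based breakpoint coordinate pairs.
#' Kilobase output rounds half-up to the nearest integer.
#'
#' @param start,end Interval coordinates (`start < end`).
#' @param unit `"bp"` (default) or `"kb"`.
#' @return Length in the requested unit.
#' @export
interval_length <- function(start, end, unit = c("bp", "kb")) {
  unit <- match.arg(unit)
  stopifnot(end > start)
  bp <- end - start
  if (unit == "bp") bp else floor(bp / 1000 + 0.5)
}

#' Filter assembly-derived indel candidates
#'
#' Keeps indels with at least `min_spanning_reads` assembly-spanning reads
#' and a protein-coding change.
#'
#' @param indels Data frame with `spanning_reads` and `coding_change`.
#' @param min_spanning_reads Support floor (default 7).
#' @return Filtered data frame.
#' @export
filter_assembly_indels <- function(indels, min_spanning_reads = 7) {
  out <- indels[indels$spanning_reads >= min_spanning_reads &
                  indels$coding_change %in% TRUE, , drop = FALSE]
  rownames(out) <- NULL
  out
}
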