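#' Hypergeometric pathway enrichment of PDS-bearing genes
#'
#' For each pathway, tests whether genes bearing possibly damaging SNVs are
#' over-represented among the pathway's members by a one-sided
#' hypergeometric (Fisher) tail: drawing `|PDS genes|` genes from the
#' universe, the p-value is the probability of observing at least the seen
#' overlap with the pathway. Results are ranked by raw p; a
#' multiple-testing adjusted column is reported alongside.
#'
#' @param pds_genes Character vector of genes bearing at least one PDS.
#' @param pathways Named list of member-gene vectors (GMT-style).
#' @param universe Gene universe; must contain all pathway members.
#' @param adjust `"BH"` (default), `"bonferroni"` or `"none"`.
#' @return Data frame ranked by `p`: `pathway`, `size`, `overlap`, `p`,
#'   `p_adjusted`, `rank`.
#' @export
pathway_enrichment <- function(pds_genes, pathways, universe,
                               adjust = c("BH", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  if (length(pathways) == 0L) stop("empty pathway collection", call. = FALSE)
  stray <- setdiff(unique(unlist(pathways)), universe)
  if (length(stray))
    stop("pathway members outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  pds_genes <- intersect(unique(pds_genes), universe)
  n_universe <- length(universe)
  n_pds <- length(pds_genes)

  rows <- lapply(names(pathways), function(pw) {
    members <- unique(pathways[[pw]])
    k <- length(intersect(members, pds_genes))
    # P(X >= k), X ~ Hypergeometric(universe, |pathway|, draws = |PDS set|)
    p <- stats::phyper(k - 1, length(members), n_universe - length(members),
                       n_pds, lower.tail = FALSE)
    data.frame(pathway = pw, size = length(members), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "none") out$p else stats::p.adjust(out$p, adjust)
  out <- out[order(out$p, out$pathway), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a GMT-style gene-set file
#'
#' Tab-separated: set name, description, then member ids.
#'
#' @param path File path.
#' @return Named list of member-gene character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[[`, "", 1L))
}

#' Write a GMT-style gene-set file
#'
#' @param sets Named list of member-gene vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
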