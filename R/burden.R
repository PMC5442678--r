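#' Classify variants as possibly damaging SNVs (PDS)
#'
#' A variant qualifies as a PDS when it is simultaneously (i) of a
#' protein-altering functional class (missense, nonsense, splice,
#' frameshift), (ii) rare under the maximum-across-sources allele-frequency
#' rule of [filter_rare()] (absence from all sources counts as rare), and
#' (iii) predicted damaging by at least `min_tools` prediction tools with
#' conservation at or above the floor, as in [filter_damaging()].
#'
#' @param variants Variant table (annotation columns `csq`, `af_*`,
#'   `dmg_*`, `cons`).
#' @param maf_threshold,min_tools,conservation_floor Rule thresholds.
#' @return Logical vector, one entry per variant row.
#' @export
classify_pds <- function(variants, maf_threshold = 0.01, min_tools = 1,
                         conservation_floor = 2) {
  functional <- variants$csq %in% FUNCTIONAL_CLASSES
  cols <- af_cols(variants)
  rare <- if (length(cols)) {
    af <- as.matrix(variants[cols])
    apply(af, 1L, function(x) all(is.na(x)) || max(x, na.rm = TRUE) <= maf_threshold)
  } else rep(TRUE, nrow(variants))
  dcols <- dmg_cols(variants)
  n_dmg <- if (length(dcols)) {
    rowSums(as.matrix(variants[dcols]) == "damaging", na.rm = TRUE)
  } else rep(0L, nrow(variants))
  damaging <- n_dmg >= min_tools & !is.na(variants$cons) &
    variants$cons >= conservation_floor
  functional & rare & damaging
}

#' Gene-wise carrier burden table for case and control cohorts
#'
#' Counts carriers at the individual level: an individual with one or more
#' qualifying variants in a gene contributes exactly once to that gene's
#' carrier count. Totals are the cohort sizes.
#'
#' @param case,control [cohort_table()] objects with identical gene
#'   universes.
#' @param genes Gene universe to tabulate over; defaults to the union of
#'   genes seen in either cohort.
#' @return Data frame with columns `gene`, `case_carriers`, `case_total`,
#'   `control_carriers`, `control_total`.
#' @export
gene_burden_table <- function(case, control, genes = NULL) {
  stopifnot(inherits(case, "cohort_table"), inherits(control, "cohort_table"))
  overlap <- intersect(case$individuals, control$individuals)
  if (length(overlap))
    stop("individual ids present in both cohorts: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  if (is.null(genes))
    genes <- sort(unique(c(case$carriers$gene, control$carriers$gene)))
  count_carriers <- function(ct) {
    u <- unique(ct$carriers[c("individual", "gene")])
    tab <- table(factor(u$gene, levels = genes))
    as.integer(tab)
  }
  data.frame(gene = genes,
             case_carriers = count_carriers(case),
             case_total = case$n,
             control_carriers = count_carriers(control),
             control_total = control$n,
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on a gene's carrier 2x2 table
#'
#' Tests carriers/non-carriers against case/control membership.
#'
#' @param burden One row of [gene_burden_table()] output (or any list with
#'   `case_carriers`, `case_total`, `control_carriers`, `control_total`).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   with `"greater"` meaning enrichment in cases.
#' @return The exact p-value.
#' @export
fisher_exact_2x2 <- function(burden, alternative = "two.sided") {
  with(as.list(burden[c("case_carriers", "case_total",
                        "control_carriers", "control_total")]), {
    if (case_total < 1 || control_total < 1)
      stop("zero-size cohort in burden table", call. = FALSE)
    if (case_carriers < 0 || control_carriers < 0 ||
        case_carriers > case_total || control_carriers > control_total)
      stop("carrier counts out of range", call. = FALSE)
    m <- matrix(c(case_carriers, case_total - case_carriers,
                  control_carriers, control_total - control_carriers),
                nrow = 2)
    stats::fisher.test(m, alternative = alternative)$p.value
  })
}

#' Candidate-gene burden scan with significance and sufficiency flags
#'
#' Applies [fisher_exact_2x2()] to each candidate gene and flags genes with
#' p below `alpha`. Genes with fewer than `min_carriers` total carriers
#' across both cohorts are flagged as having too few events for meaningful
#' statistical assessment (their p-value is still reported).
#'
#' @param case,control [cohort_table()] objects.
#' @param candidate_genes Character vector of genes to test.
#' @param alpha Significance level (default 0.05).
#' @param alternative Sidedness passed to [fisher_exact_2x2()].
#' @param min_carriers Insufficient-data floor (default 3).
#' @return Data frame: burden counts, `p`, `significant`, `insufficient`.
#' @export
burden_scan <- function(case, control, candidate_genes, alpha = 0.05,
                        alternative = "two.sided", min_carriers = 3) {
  tab <- gene_burden_table(case, control, genes = candidate_genes)
  tab$p <- vapply(seq_len(nrow(tab)), function(i)
    fisher_exact_2x2(tab[i, ], alternative = alternative), numeric(1))
  total_carriers <- tab$case_carriers + tab$control_carriers
  tab$insufficient <- total_carriers < min_carriers
  tab$significant <- tab$p < alpha & !tab$insufficient
  tab
}
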