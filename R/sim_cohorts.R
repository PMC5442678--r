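#' Simulate case and control cohorts of per-gene damaging-variant carriers
#'
#' Each individual independently carries at least one qualifying damaging
#' variant in each gene with probability `base_carrier_prob`; genes listed in
#' `enriched_genes` use `enriched_carrier_prob` in the case cohort only.
#' Carrier status is drawn per gene as a binomial count over the cohort with
#' carrier individuals then sampled uniformly without replacement, which is
#' distributionally identical to independent per-individual Bernoulli draws.
#'
#' @param config A [sim_config()]; cohort sizes, gene universe, carrier
#'   probabilities and enrichment come from it.
#' @return A list with `case` and `control` cohort tables (long format:
#'   `individual`, `gene`, `variant_key`), and `truth` holding the per-gene
#'   per-cohort carrier counts actually planted.
#' @export
simulate_cohorts <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "cohorts"))
  genes <- gene_universe(config)

  draw_cohort <- function(prefix, n, probs) {
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    counts <- rbinom(length(genes), n, probs)
    carriers <- lapply(seq_along(genes), function(i) {
      if (counts[i] == 0L) return(character(0))
      sample(ids, counts[i])
    })
    tab <- data.frame(
      individual = as.character(unlist(carriers)),
      gene = rep(genes, lengths(carriers)),
      stringsAsFactors = FALSE)
    tab$variant_key <- if (nrow(tab)) {
      paste0(tab$gene, ":pds:", seq_len(nrow(tab)))
    } else character(0)
    tab <- tab[order(tab$individual, tab$gene), ]
    rownames(tab) <- NULL
    list(table = tab, counts = stats::setNames(counts, genes), ids = ids)
  }

  case_probs <- ifelse(genes %in% config$enriched_genes,
                       config$enriched_carrier_prob, config$base_carrier_prob)
  control_probs <- rep(config$base_carrier_prob, length(genes))

  case <- draw_cohort("CASE", config$n_case, case_probs)
  control <- draw_cohort("CTRL", config$n_control, control_probs)

  list(case = cohort_table(case$table, "case", case$ids),
       control = cohort_table(control$table, "control", control$ids),
       truth = list(case_counts = as.list(case$counts),
                    control_counts = as.list(control$counts),
                    enriched_genes = config$enriched_genes),
       config = config)
}

#' Construct a cohort table of damaging-variant carriers
#'
#' @param carriers Long data frame with columns `individual`, `gene` and
#'   optionally `variant_key` (one row per carried qualifying variant).
#' @param label `"case"` or `"control"`.
#' @param individuals Full id roster (so cohort size includes non-carriers).
#' @return A `cohort_table` object.
#' @export
cohort_table <- function(carriers, label = c("case", "control"), individuals) {
  label <- match.arg(label)
  stopifnot(all(c("individual", "gene") %in% names(carriers)))
  if (anyDuplicated(individuals))
    stop("duplicate individual ids in cohort roster", call. = FALSE)
  extra <- setdiff(unique(carriers$individual), individuals)
  if (length(extra))
    stop("carriers not on the cohort roster: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  structure(list(label = label, carriers = carriers,
                 individuals = individuals, n = length(individuals)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %s: %d individuals, %d carried variants in %d genes\n",
              x$label, x$n, nrow(x$carriers), length(unique(x$carriers$gene))))
  invisible(x)
}
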