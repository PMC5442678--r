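#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the simulators behind one validated object.
#' Defaults correspond to a desk-scale emulation of a WGS trio study of
#' idiopathic intellectual disability: eight-trio-style small-variant sets,
#' a positive-control exome cohort versus a population negative-control
#' cohort, four-caller CNV/SV output, and assembly breakpoint junctions.
#'
#' @param n_sites Number of polymorphic small-variant loci per trio.
#' @param n_denovo Number of planted de novo child-only variants.
#' @param genotype_error_rate Per-genotype probability of a symmetric
#'   single-allele flip applied after Mendelian transmission.
#' @param depth_range Integer length-2, min/max simulated read depth.
#' @param mq_range Numeric length-2, min/max mapping quality.
#' @param n_case,n_control Cohort sizes for the burden study. Defaults match
#'   the secondary-control design of 2081 affected exomes versus 2535
#'   population genomes.
#' @param n_genes Size of the gene universe (`GENE1` ... `GENE<n>`).
#' @param enriched_genes Character vector of gene ids whose damaging-variant
#'   carrier probability is elevated in the case cohort only.
#' @param base_carrier_prob,enriched_carrier_prob Per-individual per-gene
#'   probability of carrying at least one qualifying damaging variant.
#' @param n_callers Number of simulated CNV callers (>= 2).
#' @param n_cnv Number of true CNV events planted per trio.
#' @param cnv_fp_rate Expected count (Poisson mean) of caller-private false
#'   positive calls per caller per sample.
#' @param boundary_jitter_bp Maximum absolute per-caller breakpoint jitter.
#' @param microhomology_len Length (bp) of the junction microhomology plant.
#' @param insert_len Integer vector of templated-insert lengths at the
#'   junction (possibly empty for a blunt or microhomology-only joint).
#' @param chrom_lengths Named integer vector of simulated chromosome lengths;
#'   must include an X chromosome for the hemizygous screen.
#' @param seed Integer top-level seed; all generators derive named
#'   substreams from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sites = 5000,
                       n_denovo = 25,
                       genotype_error_rate = 0,
                       depth_range = c(10L, 60L),
                       mq_range = c(20, 60),
                       n_case = 2081,
                       n_control = 2535,
                       n_genes = 200,
                       enriched_genes = character(),
                       base_carrier_prob = 0.002,
                       enriched_carrier_prob = 0.02,
                       n_callers = 4,
                       n_cnv = 20,
                       cnv_fp_rate = 3,
                       boundary_jitter_bp = 50,
                       microhomology_len = 14,
                       insert_len = c(24L, 107L),
                       chrom_lengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6,
                                         chrX = 5e5),
                       seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites), n_denovo = as.integer(n_denovo),
    genotype_error_rate = genotype_error_rate,
    depth_range = as.integer(depth_range), mq_range = as.numeric(mq_range),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_genes = as.integer(n_genes), enriched_genes = enriched_genes,
    base_carrier_prob = base_carrier_prob,
    enriched_carrier_prob = enriched_carrier_prob,
    n_callers = as.integer(n_callers), n_cnv = as.integer(n_cnv),
    cnv_fp_rate = cnv_fp_rate,
    boundary_jitter_bp = as.integer(boundary_jitter_bp),
    microhomology_len = as.integer(microhomology_len),
    insert_len = as.integer(insert_len),
    chrom_lengths = chrom_lengths, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why), call. = FALSE)
  }
  probs <- c(genotype_error_rate = cfg$genotype_error_rate,
             base_carrier_prob = cfg$base_carrier_prob,
             enriched_carrier_prob = cfg$enriched_carrier_prob)
  for (p in names(probs)) {
    if (!is.finite(probs[[p]]) || probs[[p]] < 0 || probs[[p]] > 1)
      bad(p, "probability must lie in [0, 1]")
  }
  if (cfg$n_denovo > cfg$n_sites) bad("n_denovo", "cannot exceed n_sites")
  if (cfg$n_denovo < 0) bad("n_denovo", "must be non-negative")
  if (cfg$enriched_carrier_prob < cfg$base_carrier_prob)
    bad("enriched_carrier_prob", "must be >= base_carrier_prob")
  if (length(cfg$depth_range) != 2L || cfg$depth_range[1] > cfg$depth_range[2])
    bad("depth_range", "must be an ordered min/max pair")
  if (length(cfg$mq_range) != 2L || cfg$mq_range[1] > cfg$mq_range[2])
    bad("mq_range", "must be an ordered min/max pair")
  if (cfg$n_case < 1 || cfg$n_control < 1)
    bad("n_case/n_control", "cohort sizes must be >= 1")
  if (cfg$n_callers < 2) bad("n_callers", "need at least two callers")
  if (cfg$cnv_fp_rate < 0) bad("cnv_fp_rate", "must be non-negative")
  if (cfg$microhomology_len < 0) bad("microhomology_len", "must be >= 0")
  if (any(cfg$insert_len < 0)) bad("insert_len", "lengths must be >= 0")
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))
    bad("chrom_lengths", "must be a named vector of positive lengths")
  universe <- gene_universe(cfg)
  missing <- setdiff(cfg$enriched_genes, universe)
  if (length(missing))
    bad("enriched_genes", paste("not in gene universe:",
                                paste(missing, collapse = ", ")))
  invisible(cfg)
}

#' Gene universe implied by a simulation config
#'
#' @param config A [sim_config()].
#' @return Character vector `GENE1 ... GENE<n_genes>`.
#' @export
gene_universe <- function(config) paste0("GENE", seq_len(config$n_genes))

#' Simulate a small multi-chromosome reference genome
#'
#' Uniform-random nucleotide sequence for each configured chromosome,
#' deterministic given `config$seed`. Used by the junction simulator and the
#' insert-origin search.
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_reference <- function(config) {
  set.seed(derive_seed(config$seed, "reference"))
  seqs <- vapply(config$chrom_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}
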