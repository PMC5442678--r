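# Shared study configuration for the analysis scripts.
#
# One synthetic trio (the "patient"), a positive-control cohort of 2081
# affected individuals versus 2535 population controls, four CNV callers,
# and a breakpoint junction with the 24 + 107 bp two-donor insertion
# architecture and a 14 bp terminal microhomology. Every script sources
# this file so that all stages share one seed and one configuration.

library(denovoscreen)

STUDY_SEED <- 20260101L

study_config <- sim_config(
  n_sites = 10000, n_denovo = 25, genotype_error_rate = 0.002,
  n_case = 2081, n_control = 2535, n_genes = 200,
  enriched_genes = c("GENE12", "GENE47", "GENE88", "GENE101", "GENE150",
                     "GENE199"),
  base_carrier_prob = 0.002, enriched_carrier_prob = 0.02,
  n_callers = 4, n_cnv = 20, cnv_fp_rate = 3, boundary_jitter_bp = 50,
  microhomology_len = 14, insert_len = c(24L, 107L),
  seed = STUDY_SEED)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
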