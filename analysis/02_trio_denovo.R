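# De novo small-variant filtration: relatedness QC, trio intersection,
# quality / rarity / functional-class / damaging filters, inheritance-model
# screens and ACMG classification of the surviving candidates.

source("analysis/00_config.R")

trio_sim <- simulate_trio(study_config)

rel_cm <- compute_relatedness(
  sample_view(trio_sim$trio, "child", carriers_only = FALSE),
  sample_view(trio_sim$trio, "mother", carriers_only = FALSE))
rel_cu <- compute_relatedness(
  sample_view(trio_sim$trio, "child", carriers_only = FALSE),
  simulate_unrelated(trio_sim, seed = STUDY_SEED + 1))
cat(sprintf("Relatedness QC: child-mother concordance %.3f vs unrelated %.3f\n",
            rel_cm, rel_cu))

cascade <- denovo_cascade(trio_sim$trio)
print(cascade$funnel)
denovoscreen:::write_tsv(cascade$funnel,
                         file.path(RESULTS_DIR, "trio_funnel.tsv"))

truth_dn <- trio_sim$truth$sites$key[trio_sim$truth$sites$label == "de_novo"]
found <- variant_key(cascade$stages$de_novo)
cat(sprintf("De novo recovery: %d/%d planted sites found, %d extra call(s) from genotype error\n",
            sum(truth_dn %in% found), length(truth_dn),
            sum(!(found %in% truth_dn))))

# inheritance models are screened over the child's rare functional variants
child_all <- sample_view(trio_sim$trio, "child")
rare_functional <- filter_functional(filter_rare(child_all))
models <- screen_inheritance_models(trio_sim$trio, rare_functional)
for (m in names(models)) {
  cat(sprintf("%-14s %d candidate(s)\n", m, nrow(models[[m]])))
  denovoscreen:::write_tsv(models[[m]],
                           file.path(RESULTS_DIR, paste0("model_", m, ".tsv")))
}

# classify the surviving damaging de novo candidates: a de novo truncating
# variant absent from controls carries PVS1 + PS2 + PM2; a de novo missense
# with computational support carries PS2 + PM2 + PP3
cand <- cascade$stages$damaging
if (nrow(cand)) {
  cand$acmg <- vapply(seq_len(nrow(cand)), function(i) {
    codes <- c("PS2", "PM2",
               if (cand$csq[i] %in% c("nonsense", "frameshift")) "PVS1",
               if (sum(cand[i, grep("^dmg_", names(cand))] == "damaging",
                       na.rm = TRUE) >= 2) "PP3")
    acmg_classify(codes)
  }, character(1))
  print(cand[c("chrom", "pos", "gene", "csq", "acmg")])
  denovoscreen:::write_tsv(cand, file.path(RESULTS_DIR, "candidates_acmg.tsv"))
}
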