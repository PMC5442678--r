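# Generate every synthetic input: trio variant sets (VCF), case/control
# cohorts, per-caller CNV call sets, the breakpoint junction, and the
# annotation tracks. Truth tables are written alongside so later stages
# can be checked against what was planted.

source("analysis/00_config.R")

out <- file.path(RESULTS_DIR, "inputs")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

trio_sim <- simulate_trio(study_config)
for (who in c("child", "mother", "father"))
  write_variant_vcf(trio_sim[[who]], file.path(out, paste0(who, ".vcf")),
                    sample_id = who)
write_pedigree(list(child = "child", father = "father", mother = "mother",
                    child_sex = attr(trio_sim$trio, "child_sex")),
               file.path(out, "pedigree.tsv"))
write_json_file <- denovoscreen:::write_json_file
write_json_file(trio_sim$truth$counts, file.path(out, "truth_trio.json"))

cat("Trio:", nrow(trio_sim$trio), "sites;",
    trio_sim$truth$counts$de_novo, "planted de novo;",
    trio_sim$truth$counts$error, "sites touched by genotype error\n")

cohorts <- simulate_cohorts(study_config)
cat("Cohorts:", cohorts$case$n, "cases /", cohorts$control$n, "controls;",
    length(study_config$enriched_genes), "genes with planted enrichment\n")

cnv_sim <- simulate_cnv_callsets(study_config)
write_cnv_calls(cnv_sim$calls, file.path(out, "cnv_calls"))
cat("CNV calls:", nrow(cnv_sim$calls), "from",
    length(cnv_sim$truth$callers), "callers;",
    sum(cnv_sim$truth$events$inheritance == "de_novo"), "planted de novo\n")

jx_sim <- simulate_junction(study_config)
cat("Junction: deletion of",
    interval_length(jx_sim$truth$deletion$start0, jx_sim$truth$deletion$end0,
                    unit = "kb"),
    "kb;", length(jx_sim$truth$inserts), "templated inserts; planted",
    nchar(jx_sim$truth$microhomology), "bp microhomology\n")

ann <- simulate_annotation_tracks(study_config)
for (cat_ in names(ann$tracks))
  write_track_bed(ann$tracks[[cat_]],
                  file.path(out, paste0("track_", cat_, ".bed")))
write_track_bed(ann$tads, file.path(out, "tads.bed"))
write_gmt(ann$pathways, file.path(out, "pathways.gmt"))
cat("Annotation:", sum(vapply(ann$tracks, nrow, integer(1))),
    "regulatory intervals in", length(ann$tracks), "categories;",
    nrow(ann$tads), "TADs\n")
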