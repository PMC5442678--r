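# Regulatory-region screen: high-confidence de novo SNVs/CNVs intersected
# with the six annotation categories, candidate-gene linkage under the
# disease-gene-screen (DDD-style) and hypothesis-driven (UPP-style) lists
# with TAD co-localization for enhancers/ultrasensitive regions, and ncRNA
# context classification.

source("analysis/00_config.R")

trio_sim <- simulate_trio(study_config)
ann <- simulate_annotation_tracks(study_config)

cnv_sim <- simulate_cnv_callsets(study_config)
calls <- cnv_sim$calls
consensus <- classify_inheritance(
  build_consensus(calls[calls$sample == "child", ]),
  calls[calls$sample == "mother", ], calls[calls$sample == "father", ])

dn <- find_de_novo(trio_sim$trio)
hc <- select_high_confidence_inputs(dn, consensus)
cat(sprintf("High-confidence inputs: %d de novo SNVs, %d de novo CNVs\n",
            nrow(hc$snvs), nrow(hc$cnvs)))

for (nm in names(ann$gene_lists)) {
  res <- screen_dvprr(hc$snvs, hc$cnvs, ann$tracks, ann$tads, ann$genes,
                      ann$gene_lists[[nm]], list_name = nm)
  cat(sprintf("[%s list, %d genes] DVPRR total %d; category hits: %s; linked to a listed gene: %d\n",
              nm, length(ann$gene_lists[[nm]]), res$funnel$dvprr_total,
              paste(sprintf("%s=%d", names(ann$tracks),
                            unlist(res$funnel[names(ann$tracks)])),
                    collapse = " "),
              res$funnel$linked))
  denovoscreen:::write_tsv(res$hits,
                           file.path(RESULTS_DIR, paste0("dvprr_", nm, ".tsv")))
  denovoscreen:::write_json_file(
    res$funnel, file.path(RESULTS_DIR, paste0("dvprr_funnel_", nm, ".json")))
}

ctx <- classify_ncrna_context(hc$snvs, ann$ncrna)
cat("ncRNA contexts:",
    paste(sprintf("%s=%d", names(ctx$counts), unlist(ctx$counts)),
          collapse = " "), "\n")
denovoscreen:::write_json_file(ctx$counts,
                               file.path(RESULTS_DIR, "ncrna_contexts.json"))
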