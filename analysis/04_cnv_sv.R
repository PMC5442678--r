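# CNV/SV analysis: multi-caller consensus by 50% reciprocal overlap,
# de novo determination against the parental call sets, high-confidence
# (>= 2 caller) classification, assembly-indel filtering, and breakpoint
# junction characterization.

source("analysis/00_config.R")

cnv_sim <- simulate_cnv_callsets(study_config)
calls <- cnv_sim$calls

caller_counts <- as.data.frame(table(caller = calls$caller, type = calls$type,
                                     sample = calls$sample))
names(caller_counts)[4] <- "count"
denovoscreen:::write_tsv(caller_counts[caller_counts$count > 0, ],
                         file.path(RESULTS_DIR, "cnv_caller_counts.tsv"))

consensus <- build_consensus(calls[calls$sample == "child", ])
consensus <- classify_inheritance(consensus,
                                  calls[calls$sample == "mother", ],
                                  calls[calls$sample == "father", ])
cat(sprintf("Child consensus: %d events from %d calls; %d high-confidence (>=2 callers); %d de novo\n",
            nrow(consensus), sum(calls$sample == "child"),
            sum(consensus$high_confidence),
            sum(consensus$inheritance == "de_novo")))
print(table(consensus$inheritance, consensus$high_confidence))
denovoscreen:::write_tsv(consensus[setdiff(names(consensus), "members")],
                         file.path(RESULTS_DIR, "cnv_consensus.tsv"))

hc_dn <- consensus[consensus$high_confidence &
                     consensus$inheritance == "de_novo", ]
if (nrow(hc_dn)) {
  cat("High-confidence de novo CNVs:\n")
  for (i in seq_len(nrow(hc_dn)))
    cat(sprintf("  %s:%d-%d %s (%s), %d kb\n", hc_dn$chrom[i],
                hc_dn$start[i], hc_dn$end[i], hc_dn$type[i],
                hc_dn$callers[i],
                interval_length(hc_dn$start[i], hc_dn$end[i], unit = "kb")))
}

indels <- filter_assembly_indels(simulate_assembly_indels(study_config)$indels)
cat(sprintf("Assembly indels: %d pass >=7 spanning reads + coding change\n",
            nrow(indels)))
denovoscreen:::write_tsv(indels,
                         file.path(RESULTS_DIR, "assembly_indels.tsv"))

jx_sim <- simulate_junction(study_config)
jx <- classify_junction(jx_sim$junction, jx_sim$reference)
cat(sprintf("Junction signature: %s; microhomology %s (%d bp); inserts: %s\n",
            jx$signature, jx$microhomology$seq, jx$microhomology$length,
            paste(vapply(jx$inserts, function(x)
              sprintf("%d bp from %s", nchar(x$seq), x$chrom), character(1)),
              collapse = ", ")))
denovoscreen:::write_json_file(
  list(signature = jx$signature, microhomology = jx$microhomology,
       inserts = lapply(jx$inserts, function(x)
         x[c("chrom", "start0", "end0")])),
  file.path(RESULTS_DIR, "junction_report.json"))

per_chrom <- as.data.frame(table(chrom = calls$chrom[calls$sample == "child"]))
names(per_chrom)[2] <- "count"
denovoscreen:::write_tsv(per_chrom,
                         file.path(RESULTS_DIR, "events_per_chromosome.tsv"))
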