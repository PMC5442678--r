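#' Run the full synthetic-trio analysis pipeline
#'
#' Orchestrates every stage end to end on one simulated trio and cohort
#' pair: input generation (variant VCFs, CNV call sets, junction contig,
#' annotation tracks), de novo small-variant filtration and inheritance
#' screens, case/control burden testing with the gene-set bootstrap and
#' pathway enrichment, CNV/SV consensus with inheritance and junction
#' characterization, and the regulatory-region (DVPRR) screens. All stage
#' outputs are written under `out_dir` together with a machine-readable
#' manifest listing each artifact with its MD5 checksum and the effective
#' configuration.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param flank_bp,ro_threshold,alpha,reps,set_size Stage thresholds.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, flank_bp = 10000,
                         ro_threshold = 0.5, alpha = 0.05, reps = 1000,
                         set_size = 6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))

  # --- simulate -----------------------------------------------------------
  trio_sim <- simulate_trio(config)
  cohorts <- simulate_cohorts(config)
  cnv_sim <- simulate_cnv_callsets(config)
  jx_sim <- simulate_junction(config)
  ann <- simulate_annotation_tracks(config)
  indel_sim <- simulate_assembly_indels(config)

  for (who in c("child", "mother", "father"))
    write_variant_vcf(trio_sim[[who]], file.path(out_dir, paste0(who, ".vcf")),
                      sample_id = who)
  write_pedigree(list(child = "child", father = "father", mother = "mother",
                      child_sex = attr(trio_sim$trio, "child_sex")),
                 file.path(out_dir, "pedigree.tsv"))
  write_cnv_calls(cnv_sim$calls, file.path(out_dir, "cnv_calls"))
  for (cat in names(ann$tracks))
    write_track_bed(ann$tracks[[cat]],
                    file.path(out_dir, paste0("track_", cat, ".bed")))
  write_track_bed(ann$tads, file.path(out_dir, "tads.bed"))
  write_gmt(ann$pathways, file.path(out_dir, "pathways.gmt"))
  for (nm in names(ann$gene_lists))
    writeLines(ann$gene_lists[[nm]],
               file.path(out_dir, paste0("genelist_", nm, ".txt")))
  write_json_file(trio_sim$truth$counts, file.path(out_dir, "truth_trio.json"))

  # --- trio de novo cascade ----------------------------------------------
  relatedness <- list(
    child_mother = compute_relatedness(sample_view(trio_sim$trio, "child",
                                                   carriers_only = FALSE),
                                       sample_view(trio_sim$trio, "mother",
                                                   carriers_only = FALSE)),
    child_father = compute_relatedness(sample_view(trio_sim$trio, "child",
                                                   carriers_only = FALSE),
                                       sample_view(trio_sim$trio, "father",
                                                   carriers_only = FALSE)))
  cascade <- denovo_cascade(trio_sim$trio)
  for (i in seq_along(cascade$stages))
    log_stage(names(cascade$stages)[i],
              if (i == 1L) nrow(trio_sim$trio) else
                nrow(cascade$stages[[i - 1L]]),
              nrow(cascade$stages[[i]]))
  rare_functional <- filter_functional(filter_rare(
    sample_view(trio_sim$trio, "child")))
  models <- screen_inheritance_models(trio_sim$trio, rare_functional)
  write_tsv(cascade$funnel, file.path(out_dir, "trio_funnel.tsv"))
  write_json_file(stats::setNames(as.list(cascade$funnel$count),
                                  cascade$funnel$stage),
                  file.path(out_dir, "trio_funnel.json"))
  for (m in names(models))
    write_tsv(models[[m]], file.path(out_dir, paste0("model_", m, ".tsv")))
  write_tsv(cascade$stages$damaging, file.path(out_dir, "candidates.tsv"))

  # --- burden study -------------------------------------------------------
  universe <- gene_universe(config)
  candidate_genes <- if (length(config$enriched_genes))
    config$enriched_genes else utils::head(universe, set_size)
  scan <- burden_scan(cohorts$case, cohorts$control, candidate_genes,
                      alpha = alpha)
  boot <- bootstrap_gene_sets(cohorts$case, candidate_genes, universe,
                              reps = reps, set_size = min(set_size,
                                                          length(candidate_genes)),
                              seed = config$seed)
  burden_all <- gene_burden_table(cohorts$case, cohorts$control,
                                  genes = universe)
  # pathway enrichment over the high-burden tail: at cohort scale nearly
  # every gene has some carrier, so the informative set is the top decile
  pds_genes <- burden_all$gene[burden_all$case_carriers >=
                                 stats::quantile(burden_all$case_carriers, 0.9)]
  enrich <- pathway_enrichment(pds_genes, ann$pathways, universe)
  write_tsv(scan, file.path(out_dir, "burden_scan.tsv"))
  write_tsv(data.frame(rep = seq_along(boot$mean$null),
                       null_mean = boot$mean$null,
                       null_median = boot$median$null),
            file.path(out_dir, "bootstrap_null.tsv"))
  write_tsv(enrich, file.path(out_dir, "pathway_enrichment.tsv"))
  log_stage("burden_scan", length(candidate_genes), sum(scan$significant))

  # --- CNV/SV -------------------------------------------------------------
  calls <- cnv_sim$calls
  child_calls <- calls[calls$sample == "child", , drop = FALSE]
  consensus <- build_consensus(child_calls, ro_threshold = ro_threshold)
  consensus <- classify_inheritance(
    consensus, calls[calls$sample == "mother", , drop = FALSE],
    calls[calls$sample == "father", , drop = FALSE],
    ro_threshold = ro_threshold)
  jx <- classify_junction(jx_sim$junction, jx_sim$reference)
  indels <- filter_assembly_indels(indel_sim$indels)
  write_tsv(consensus[setdiff(names(consensus), "members")],
            file.path(out_dir, "cnv_consensus.tsv"))
  write_json_file(list(signature = jx$signature,
                       microhomology = jx$microhomology,
                       inserts = lapply(jx$inserts, function(x)
                         x[c("chrom", "start0", "end0")])),
                  file.path(out_dir, "junction_report.json"))
  write_tsv(indels, file.path(out_dir, "assembly_indels_filtered.tsv"))
  log_stage("cnv_consensus", nrow(child_calls), nrow(consensus))

  # --- regulatory ---------------------------------------------------------
  hc <- select_high_confidence_inputs(cascade$stages$de_novo, consensus)
  dvprr <- lapply(names(ann$gene_lists), function(nm)
    screen_dvprr(hc$snvs, hc$cnvs, ann$tracks, ann$tads, ann$genes,
                 ann$gene_lists[[nm]], list_name = nm, flank_bp = flank_bp))
  names(dvprr) <- names(ann$gene_lists)
  ncrna_ctx <- classify_ncrna_context(hc$snvs, ann$ncrna)
  for (nm in names(dvprr)) {
    write_tsv(dvprr[[nm]]$hits,
              file.path(out_dir, paste0("dvprr_", nm, ".tsv")))
    write_json_file(dvprr[[nm]]$funnel,
                    file.path(out_dir, paste0("dvprr_funnel_", nm, ".json")))
  }
  write_json_file(ncrna_ctx$counts, file.path(out_dir, "ncrna_contexts.json"))
  log_stage("dvprr", nrow(hc$snvs) + nrow(hc$cnvs),
            sum(vapply(dvprr, function(d) nrow(d$hits), integer(1))))

  results <- list(trio_sim = trio_sim, cohorts = cohorts, cnv_sim = cnv_sim,
                  jx_sim = jx_sim, ann = ann, indel_sim = indel_sim,
                  relatedness = relatedness, cascade = cascade,
                  models = models, scan = scan, boot = boot,
                  enrich = enrich, consensus = consensus, junction = jx,
                  indels = indels, hc = hc, dvprr = dvprr,
                  ncrna = ncrna_ctx, config = config)
  write_report(results, out_dir)

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    config = unclass(config)[setdiff(names(config), "chrom_lengths")],
    chrom_lengths = as.list(config$chrom_lengths),
    artifacts = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

#' Write the per-patient summary report
#'
#' A pure view over the stage outputs: the trio filtration funnel, the
#' DVPRR funnels, a per-caller CNV/SV count table, the burden summary with
#' flagged genes, bootstrap null-distribution histogram data and
#' per-chromosome event counts.
#'
#' @param results Stage results from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Invisibly, the report list.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- results$cnv_sim$calls
  caller_table <- as.data.frame(table(caller = calls$caller,
                                      type = calls$type,
                                      sample = calls$sample),
                                stringsAsFactors = FALSE)
  names(caller_table)[4] <- "count"
  caller_table <- caller_table[caller_table$count > 0L, , drop = FALSE]
  per_chrom <- as.data.frame(table(chrom = calls$chrom[calls$sample == "child"]),
                             stringsAsFactors = FALSE)
  names(per_chrom)[2] <- "count"
  hist_breaks <- pretty(results$boot$mean$null, 20)
  h <- hist(results$boot$mean$null, breaks = hist_breaks, plot = FALSE)
  report <- list(
    trio_funnel = stats::setNames(as.list(results$cascade$funnel$count),
                                  results$cascade$funnel$stage),
    relatedness = results$relatedness,
    burden = list(
      candidates = results$scan$gene,
      significant = results$scan$gene[results$scan$significant],
      insufficient = results$scan$gene[results$scan$insufficient],
      bootstrap_p_mean = results$boot$mean$p,
      bootstrap_p_median = results$boot$median$p),
    dvprr_funnels = lapply(results$dvprr, `[[`, "funnel"),
    ncrna_contexts = results$ncrna$counts,
    junction_signature = results$junction$signature)
  write_tsv(caller_table, file.path(out_dir, "cnv_caller_counts.tsv"))
  write_tsv(per_chrom, file.path(out_dir, "events_per_chromosome.tsv"))
  write_tsv(data.frame(bin_mid = h$mids, count = h$counts),
            file.path(out_dir, "bootstrap_hist.tsv"))
  write_json_file(report, file.path(out_dir, "report.json"))
  invisible(report)
}
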