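#' Classify de novo SNVs by ncRNA gene context
#'
#' Each SNV overlapping an ncRNA gene body is assigned exactly one context
#' label with precedence `splice_junction` > `exonic` > `UTR5`/`UTR3` >
#' `intronic`. A splice-junction position lies within 2 bases of an exon
#' boundary (the canonical splice-site span). UTR labels apply to the
#' terminal `utr_len` bases at each end of the gene body, the
#' lower-coordinate end taken as 5' (the simulated models are unstranded);
#' exonic positions take precedence. SNVs overlapping no ncRNA gene are
#' excluded from the counts.
#'
#' @param snvs SNV table with `chrom` and 1-based `pos`.
#' @param ncrna ncRNA exon table (`gene_id`, `chrom`, `start0`, `end0`,
#'   `exon`), exons ordered by `exon` within gene.
#' @param splice_window Bases around an exon boundary that count as splice
#'   junction (default 2).
#' @param utr_len Terminal span treated as UTR (default 100 bp).
#' @return List with `contexts` (per-SNV label, `NA` when outside all
#'   ncRNA) and `counts` (named totals).
#' @export
classify_ncrna_context <- function(snvs, ncrna, splice_window = 2L,
                                   utr_len = 100L) {
  labels <- c("splice_junction", "exonic", "UTR5", "UTR3", "intronic")
  genes <- split(ncrna, ncrna$gene_id)
  ctx <- rep(NA_character_, nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    p0 <- snvs$pos[i] - 1L  # 0-based position
    for (g in genes) {
      if (g$chrom[1] != snvs$chrom[i]) next
      body_s <- min(g$start0); body_e <- max(g$end0)
      if (p0 < body_s || p0 >= body_e) next
      bounds <- c(g$start0, g$end0)
      in_exon <- any(p0 >= g$start0 & p0 < g$end0)
      near_bound <- any(abs(p0 - bounds) <= splice_window |
                          abs(p0 - (bounds - 1L)) <= splice_window)
      ctx[i] <- if (near_bound) "splice_junction"
      else if (in_exon) "exonic"
      else if (p0 < body_s + utr_len) "UTR5"
      else if (p0 >= body_e - utr_len) "UTR3"
      else "intronic"
      break
    }
  }
  counts <- vapply(labels, function(l) sum(ctx %in% l), integer(1))
  list(contexts = ctx, counts = as.list(counts))
}
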