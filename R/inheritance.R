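#' Screen trio variants under Mendelian inheritance models
#'
#' Classifies rare functional candidate variants under four genetic models:
#'
#' * `de_novo_het`: child heterozygous, both parents homozygous reference;
#' * `hom_recessive`: child homozygous alternate, both parents heterozygous;
#' * `comp_het`: a gene carrying two or more rare functional heterozygous
#'   child variants with at least one transmitted from each parent.
#'   Parental origin is inferred by exclusion from unphased genotypes (a
#'   site counts as maternal when only the mother carries the allele);
#'   sites carried by both parents are origin-ambiguous, dropped from this
#'   model and counted in attribute `n_ambiguous`;
#' * `hemizygous`: X-chromosome variant in a male child carrying the
#'   allele, mother heterozygous, father not carrying it.
#'
#' @param trio Trio site table (see [simulate_trio()]); attribute
#'   `child_sex` governs the hemizygous screen.
#' @param candidates Optional child-view variant table of rare functional
#'   variants (e.g. output of [filter_functional()] after [filter_rare()]);
#'   defaults to all child-carried sites.
#' @param x_chrom Name of the X chromosome (default `"chrX"`).
#' @return Named list of candidate tables, one per model, with attribute
#'   `n_ambiguous` on the `comp_het` element.
#' @export
screen_inheritance_models <- function(trio, candidates = NULL,
                                      x_chrom = "chrX") {
  child_sex <- attr(trio, "child_sex")
  if (is.null(child_sex)) child_sex <- "unknown"
  key <- variant_key(trio)
  if (is.null(candidates)) {
    cand_keys <- key[gt_carries_alt(trio$gt_child) %in% TRUE]
  } else {
    cand_keys <- variant_key(candidates)
  }
  idx <- match(cand_keys, key)
  idx <- idx[!is.na(idx)]
  sub <- trio[idx, , drop = FALSE]

  child_view <- function(rows) {
    out <- sample_view(rows, "child", carriers_only = FALSE)
    rownames(out) <- NULL
    out
  }

  dn <- gt_is_het(sub$gt_child) &
    gt_is_hom_ref(sub$gt_mother) & gt_is_hom_ref(sub$gt_father)
  hom <- gt_is_hom_alt(sub$gt_child) &
    gt_is_het(sub$gt_mother) & gt_is_het(sub$gt_father)
  hemi <- sub$chrom == x_chrom & child_sex == "male" &
    gt_carries_alt(sub$gt_child) %in% TRUE &
    gt_is_het(sub$gt_mother) &
    gt_carries_alt(sub$gt_father) %in% FALSE

  # compound heterozygous: phase by parental exclusion
  het <- gt_is_het(sub$gt_child)
  mother_carries <- gt_carries_alt(sub$gt_mother) %in% TRUE
  father_carries <- gt_carries_alt(sub$gt_father) %in% TRUE
  origin <- rep(NA_character_, nrow(sub))
  origin[het & mother_carries & !father_carries] <- "maternal"
  origin[het & !mother_carries & father_carries] <- "paternal"
  ambiguous <- het & mother_carries & father_carries
  ch_rows <- integer(0)
  for (g in unique(sub$gene[het & !is.na(sub$gene)])) {
    in_gene <- which(sub$gene %in% g & het & !ambiguous)
    orig <- origin[in_gene]
    if (length(in_gene) >= 2L && any(orig %in% "maternal") &&
        any(orig %in% "paternal"))
      ch_rows <- c(ch_rows, in_gene)
  }
  comp_het <- child_view(sub[sort(ch_rows), , drop = FALSE])
  attr(comp_het, "n_ambiguous") <- sum(ambiguous, na.rm = TRUE)

  list(de_novo_het = child_view(sub[which(dn), , drop = FALSE]),
       hom_recessive = child_view(sub[which(hom), , drop = FALSE]),
       comp_het = comp_het,
       hemizygous = child_view(sub[which(hemi), , drop = FALSE]))
}
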