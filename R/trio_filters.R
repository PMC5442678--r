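FUNCTIONAL_CLASSES <- c("missense", "nonsense", "splice", "frameshift")

#' Genotype concordance between two samples (relatedness QC)
#'
#' Fraction of jointly genotyped sites with identical genotypes. Used as a
#' pedigree sanity check: a true parent-child pair shows markedly higher
#' concordance than an unrelated pair.
#'
#' @param sample_a,sample_b Variant tables with columns `chrom`, `pos`,
#'   `ref`, `alt` and `gt`.
#' @return Concordance fraction in `[0, 1]`.
#' @export
compute_relatedness <- function(sample_a, sample_b) {
  ka <- variant_key(sample_a); kb <- variant_key(sample_b)
  shared <- intersect(ka, kb)
  ga <- gt_normalize(sample_a$gt[match(shared, ka)])
  gb <- gt_normalize(sample_b$gt[match(shared, kb)])
  ok <- !gt_is_missing(ga) & !gt_is_missing(gb) & gt_is_valid(ga) & gt_is_valid(gb)
  if (!any(ok))
    stop("no jointly genotyped sites between the two samples", call. = FALSE)
  mean(ga[ok] == gb[ok])
}

#' Identify de novo variants by trio intersection
#'
#' A child variant is de novo when the child carries the alternate allele
#' and the allele is absent from both parental genotypes at that site.
#' Sites with malformed genotypes in any trio member are skipped with a
#' warning; the skip count is attached as attribute `n_skipped`.
#'
#' @param trio Trio site table (columns `gt_child`, `gt_mother`,
#'   `gt_father`, plus the child's `dp_child`/`mq_child` and annotations),
#'   as produced by [simulate_trio()].
#' @return The child's de novo variant table (child view: `gt`, `dp`, `mq`
#'   plus annotations), with attribute `n_skipped`.
#' @export
find_de_novo <- function(trio) {
  gts <- cbind(trio$gt_child, trio$gt_mother, trio$gt_father)
  malformed <- !gt_is_valid(gts[, 1]) | !gt_is_valid(gts[, 2]) |
    !gt_is_valid(gts[, 3])
  if (any(malformed))
    warning(sum(malformed), " site(s) with malformed genotypes skipped")
  keep <- !malformed &
    gt_carries_alt(trio$gt_child) %in% TRUE &
    gt_carries_alt(trio$gt_mother) %in% FALSE &
    gt_carries_alt(trio$gt_father) %in% FALSE
  out <- sample_view(trio[keep, , drop = FALSE], "child", carriers_only = FALSE)
  attr(out, "n_skipped") <- sum(malformed)
  out
}

#' High-confidence variant filter (mapping quality and depth)
#'
#' Keeps variants with mapping quality strictly greater than `min_mapq` and
#' read depth within `[min_depth, max_depth]`. Records missing either
#' quality field are excluded and counted (attribute `n_missing_quality`).
#'
#' @param variants Variant table with `mq` and `dp` columns.
#' @param min_mapq Exclusive mapping-quality bound (default 30).
#' @param min_depth,max_depth Inclusive depth bounds (default 10 and 100).
#' @return Filtered variant table.
#' @export
filter_high_confidence <- function(variants, min_mapq = 30,
                                   min_depth = 10, max_depth = 100) {
  missing_q <- is.na(variants$mq) | is.na(variants$dp)
  keep <- !missing_q & variants$mq > min_mapq &
    variants$dp >= min_depth & variants$dp <= max_depth
  out <- variants[keep, , drop = FALSE]
  attr(out, "n_missing_quality") <- sum(missing_q)
  rownames(out) <- NULL
  out
}

#' Rarity filter across population frequency sources
#'
#' A variant is excluded when its maximum allele frequency across all
#' populated `af_*` sources exceeds `threshold`; absence from every source
#' is treated as rare (exclusion requires positive evidence of commonness).
#'
#' @param variants Variant table with zero or more `af_*` columns.
#' @param threshold Maximum tolerated allele frequency (default 0.01).
#' @return Filtered variant table.
#' @export
filter_rare <- function(variants, threshold = 0.01) {
  cols <- af_cols(variants)
  if (length(cols) == 0L) return(variants)
  af <- as.matrix(variants[cols])
  max_af <- apply(af, 1L, function(x) if (all(is.na(x))) -Inf else max(x, na.rm = TRUE))
  out <- variants[max_af <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Functional-class filter
#'
#' Keeps protein-altering consequence classes: missense, nonsense, splice
#' and frameshift. Unknown consequence labels are excluded with a warning.
#'
#' @param variants Variant table with a `csq` column.
#' @return Filtered variant table.
#' @export
filter_functional <- function(variants) {
  unknown <- !(variants$csq %in% CSQ_CLASSES) & !is.na(variants$csq)
  if (any(unknown))
    warning(sum(unknown), " record(s) with unknown consequence label excluded")
  out <- variants[variants$csq %in% FUNCTIONAL_CLASSES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Damaging-prediction filter with conservation floor
#'
#' Keeps variants called damaging by at least `min_tools` prediction tools
#' (`dmg_*` columns) and with conservation score at or above
#' `conservation_floor`; both conditions must hold ("highly conserved and
#' predicted to be damaging").
#'
#' @param variants Variant table with `dmg_*` columns and `cons`.
#' @param min_tools Minimum count of tools calling damaging (default 1).
#' @param conservation_floor PhyloP-style score floor (default 2).
#' @return Filtered variant table.
#' @export
filter_damaging <- function(variants, min_tools = 1, conservation_floor = 2) {
  cols <- dmg_cols(variants)
  n_dmg <- if (length(cols)) {
    rowSums(as.matrix(variants[cols]) == "damaging", na.rm = TRUE)
  } else rep(0L, nrow(variants))
  keep <- n_dmg >= min_tools & !is.na(variants$cons) &
    variants$cons >= conservation_floor
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filtration funnel report
#'
#' Summarizes an ordered filtration cascade as stage-wise counts and checks
#' the monotonicity contract: each successive stage must be a subset of the
#' previous one.
#'
#' @param stages Named list of variant tables in filtration order.
#' @return Data frame with columns `stage` and `count`.
#' @export
build_funnel <- function(stages) {
  counts <- vapply(stages, nrow, integer(1))
  if (any(diff(counts) > 0L))
    stop("funnel violation: stage '",
         names(stages)[which(diff(counts) > 0L)[1] + 1L],
         "' has more records than its predecessor", call. = FALSE)
  data.frame(stage = names(stages), count = unname(counts),
             stringsAsFactors = FALSE)
}

#' Run the full de novo small-variant filtration cascade
#'
#' Trio intersection, then quality, rarity, functional-class and
#' damaging-prediction filters in the declared order.
#'
#' @param trio Trio site table.
#' @param maf_threshold,min_mapq,min_depth,max_depth,min_tools,conservation_floor
#'   Stage thresholds, see the individual filters.
#' @return List with `stages` (variant table per stage) and `funnel`
#'   (stage-count report).
#' @export
denovo_cascade <- function(trio, maf_threshold = 0.01, min_mapq = 30,
                           min_depth = 10, max_depth = 100, min_tools = 1,
                           conservation_floor = 2) {
  dn <- find_de_novo(trio)
  stages <- list(de_novo = dn)
  stages$high_confidence <- filter_high_confidence(dn, min_mapq, min_depth,
                                                   max_depth)
  stages$rare <- filter_rare(stages$high_confidence, maf_threshold)
  stages$functional <- filter_functional(stages$rare)
  stages$damaging <- filter_damaging(stages$functional, min_tools,
                                     conservation_floor)
  list(stages = stages, funnel = build_funnel(stages))
}
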