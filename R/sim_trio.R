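CSQ_CLASSES <- c("missense", "nonsense", "splice", "frameshift", "synonymous",
                 "intronic", "intergenic", "UTR5", "UTR3",
                 "ncRNA_exonic", "ncRNA_intronic")

FREQ_SOURCES <- c("dbsnp", "evs", "exac", "inhouse")
DMG_TOOLS <- c("sift", "polyphen", "mutationtaster", "cadd")

#' Simulate an annotated WGS trio with planted de novo variants
#'
#' Draws polymorphic sites across the configured chromosomes, assigns
#' parental genotypes under Hardy-Weinberg from a per-site allele frequency,
#' transmits alleles to the child under Mendelian rules (maternal-only on X
#' for a male child), plants exactly `n_denovo` child-only heterozygous
#' variants at sites where both parents are homozygous reference, and then
#' applies symmetric single-allele genotype flips at
#' `genotype_error_rate` per genotype. Depth and mapping quality are drawn
#' uniformly from the configured ranges per sample per site.
#'
#' Annotation fields (consequence class, gene id, per-source allele
#' frequencies, per-tool damaging calls, conservation score) are written by
#' the generator rather than computed from sequence: the filtration logic
#' under test starts downstream of annotation, as it would with externally
#' annotated VCFs.
#'
#' Truth labels (one per site): `de_novo` (planted), `error` (a genotype at
#' the site was perturbed), `inherited_mat` / `inherited_pat` /
#' `inherited_both` (origin of the child's alt allele(s)), or `hom_ref`
#' (child carries no alt).
#'
#' @param config A [sim_config()].
#' @param child_sex `"male"` or `"female"`; male children are hemizygous on X.
#' @return A list with elements `trio` (site-by-sample table with genotypes
#'   `gt_child`/`gt_mother`/`gt_father`, qualities, and annotation columns),
#'   `child`/`mother`/`father` (per-individual variant tables restricted to
#'   alt-carrying sites, columns `gt`/`dp`/`mq` plus annotations), `truth`
#'   (per-site labels and summary counts), `sites` (per-site allele
#'   frequencies), and the effective `config`.
#' @export
simulate_trio <- function(config, child_sex = c("male", "female")) {
  validate_sim_config(config)
  child_sex <- match.arg(child_sex)
  set.seed(derive_seed(config$seed, "trio"))

  n <- config$n_sites
  chroms <- names(config$chrom_lengths)
  chrom <- sample(chroms, n, replace = TRUE,
                  prob = config$chrom_lengths / sum(config$chrom_lengths))
  pos <- vapply(chrom, function(cc) sample.int(config$chrom_lengths[[cc]], 1L),
                integer(1))
  ord <- order(match(chrom, chroms), pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  # mixture of rare and common site frequencies
  rare <- runif(n) < 0.3
  maf <- ifelse(rare, runif(n, 5e-4, 9e-3), runif(n, 0.05, 0.5))

  on_x <- chrom == "chrX"
  male_child <- child_sex == "male"

  draw_diploid <- function(p) {
    a1 <- rbinom(length(p), 1L, p); a2 <- rbinom(length(p), 1L, p)
    paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  }
  draw_hemi <- function(p) as.character(rbinom(length(p), 1L, p))

  gt_mother <- draw_diploid(maf)
  gt_father <- ifelse(on_x, draw_hemi(maf), draw_diploid(maf))

  transmit <- function(gt) {
    # one allele uniformly at random from a diploid genotype
    al <- strsplit(gt_normalize(gt), "/", fixed = TRUE)
    pick <- runif(length(al)) < 0.5
    vapply(seq_along(al), function(i) {
      a <- al[[i]]
      if (length(a) == 1L) a else a[if (pick[i]) 1L else 2L]
    }, character(1))
  }

  mat_allele <- transmit(gt_mother)
  pat_allele <- transmit(gt_father)
  gt_child <- ifelse(on_x & male_child, mat_allele,
                     paste(pmin(mat_allele, pat_allele),
                           pmax(mat_allele, pat_allele), sep = "/"))
  if (male_child) pat_allele[on_x] <- "0"  # no paternal X transmission to sons

  # plant de novo variants where both parents are hom-ref
  candidates <- which(gt_is_hom_ref(gt_mother) & gt_is_hom_ref(gt_father))
  if (length(candidates) < config$n_denovo)
    stop("too few double-hom-ref sites to plant ", config$n_denovo,
         " de novo variants; increase n_sites", call. = FALSE)
  dn_idx <- sort(sample(candidates, config$n_denovo))
  gt_child[dn_idx] <- ifelse(on_x[dn_idx] & male_child, "1", "0/1")
  # the planted allele must not also be transmitted
  mat_allele[dn_idx] <- "0"; pat_allele[dn_idx] <- "0"

  truth_label <- rep("hom_ref", n)
  truth_label[mat_allele == "1" & pat_allele != "1"] <- "inherited_mat"
  truth_label[pat_allele == "1" & mat_allele != "1"] <- "inherited_pat"
  truth_label[mat_allele == "1" & pat_allele == "1"] <- "inherited_both"
  truth_label[on_x & male_child & mat_allele == "1"] <- "inherited_mat"
  truth_label[dn_idx] <- "de_novo"

  flip_one <- function(gt) {
    # symmetric single-allele flip
    vapply(gt, function(g) {
      if (g %in% c("0", "1")) return(if (g == "0") "1" else "0")
      a <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
      i <- sample(1:2, 1L)
      a[i] <- 1L - a[i]
      paste(min(a), max(a), sep = "/")
    }, character(1), USE.NAMES = FALSE)
  }
  err_any <- rep(FALSE, n)
  if (config$genotype_error_rate > 0) {
    for (who in c("child", "mother", "father")) {
      col <- paste0("gt_", who)
      g <- get(col)
      hit <- which(runif(n) < config$genotype_error_rate)
      if (length(hit)) {
        g[hit] <- flip_one(g[hit])
        assign(col, g)
        err_any[hit] <- TRUE
      }
    }
    truth_label[err_any] <- "error"
  }

  rint <- function() sample(config$depth_range[1]:config$depth_range[2], n,
                            replace = TRUE)
  runi <- function() round(runif(n, config$mq_range[1], config$mq_range[2]), 1)

  # annotations written by the generator (see Details)
  csq <- sample(CSQ_CLASSES, n, replace = TRUE,
                prob = c(.10, .02, .02, .02, .08, .30, .28, .03, .03, .04, .08))
  genic <- csq != "intergenic"
  gene <- ifelse(genic, sample(gene_universe(config), n, replace = TRUE),
                 NA_character_)
  af <- matrix(NA_real_, n, length(FREQ_SOURCES),
               dimnames = list(NULL, paste0("af_", FREQ_SOURCES)))
  for (j in seq_along(FREQ_SOURCES)) {
    present <- runif(n) < 0.8
    present[dn_idx] <- FALSE  # a new mutation is absent from databases
    af[present, j] <- pmin(1, pmax(0, maf[present] * runif(n, 0.5, 1.5)[present]))
  }
  p_dmg <- ifelse(csq %in% c("nonsense", "frameshift", "splice"), 0.8,
                  ifelse(csq == "missense", 0.35, 0.05))
  dmg <- matrix(NA_character_, n, length(DMG_TOOLS),
                dimnames = list(NULL, paste0("dmg_", DMG_TOOLS)))
  for (j in seq_along(DMG_TOOLS)) {
    present <- runif(n) < 0.9
    dmg[present, j] <- ifelse(runif(sum(present)) < p_dmg[present],
                              "damaging", "tolerated")
  }
  cons <- round(rnorm(n, 1.0, 1.8), 3)

  trio <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gt_child = gt_child, gt_mother = gt_mother, gt_father = gt_father,
    dp_child = rint(), dp_mother = rint(), dp_father = rint(),
    mq_child = runi(), mq_mother = runi(), mq_father = runi(),
    csq = csq, gene = gene, stringsAsFactors = FALSE)
  trio <- cbind(trio, as.data.frame(af), as.data.frame(dmg, stringsAsFactors = FALSE))
  trio$cons <- cons
  attr(trio, "child_sex") <- child_sex

  truth_sites <- data.frame(key = variant_key(trio), label = truth_label,
                            stringsAsFactors = FALSE)
  truth <- list(
    sites = truth_sites,
    counts = as.list(table(factor(truth_label,
      levels = c("de_novo", "inherited_mat", "inherited_pat",
                 "inherited_both", "hom_ref", "error")))))

  list(trio = trio,
       child = sample_view(trio, "child"),
       mother = sample_view(trio, "mother"),
       father = sample_view(trio, "father"),
       truth = truth,
       sites = data.frame(key = truth_sites$key, maf = maf,
                          stringsAsFactors = FALSE),
       config = config)
}

#' Extract one individual's variant table from a trio site table
#'
#' @param trio Trio site table from [simulate_trio()].
#' @param who `"child"`, `"mother"` or `"father"`.
#' @param carriers_only Keep only alt-carrying sites (the individual's
#'   variant set, as a per-sample VCF would contain)?
#' @return Variant table with columns `gt`, `dp`, `mq` plus annotations.
#' @export
sample_view <- function(trio, who = c("child", "mother", "father"),
                        carriers_only = TRUE) {
  who <- match.arg(who)
  keep <- c("chrom", "pos", "ref", "alt")
  out <- trio[keep]
  out$gt <- trio[[paste0("gt_", who)]]
  out$dp <- trio[[paste0("dp_", who)]]
  out$mq <- trio[[paste0("mq_", who)]]
  ann <- setdiff(names(trio), c(keep, grep("^(gt|dp|mq)_", names(trio), value = TRUE)))
  out <- cbind(out, trio[ann])
  if (carriers_only) out <- out[gt_carries_alt(out$gt) %in% TRUE, ]
  rownames(out) <- NULL
  out
}

#' Simulate genotypes for an unrelated individual at a trio's sites
#'
#' Draws Hardy-Weinberg genotypes at the same loci and allele frequencies as
#' an existing trio simulation, independent of the family's genotypes. Used
#' to check that trio relatedness exceeds that of an unrelated pair.
#'
#' @param trio_sim Result of [simulate_trio()].
#' @param seed Integer seed for the unrelated draw.
#' @return Variant table (all sites, `carriers_only = FALSE` semantics).
#' @export
simulate_unrelated <- function(trio_sim, seed) {
  set.seed(derive_seed(seed, "unrelated"))
  maf <- trio_sim$sites$maf
  a1 <- rbinom(length(maf), 1L, maf); a2 <- rbinom(length(maf), 1L, maf)
  out <- trio_sim$trio[c("chrom", "pos", "ref", "alt")]
  out$gt <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  out
}
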