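test_that("de novo identification follows the trio-intersection rule", {
  trio <- make_trio_sites(
    gt_child = c("0/1", "0/1", "0/1", "1/1", "0/0"),
    gt_mother = c("0/1", "0/0", "0/0", "0/1", "0/0"),
    gt_father = c("0/0", "0/0", "0/1", "0/1", "0/0"))
  dn <- find_de_novo(trio)
  # only the child-only site survives; transmitted and hom-ref sites do not
  expect_equal(dn$pos, 2000L)
  expect_equal(attr(dn, "n_skipped"), 0L)
})

test_that("malformed genotypes are skipped with a warning and counted", {
  trio <- make_trio_sites(
    gt_child = c("0/1", "0/2", "0/1"),
    gt_mother = c("0/0", "0/0", "XX"),
    gt_father = c("0/0", "0/0", "0/0"))
  expect_warning(dn <- find_de_novo(trio), "malformed")
  expect_equal(nrow(dn), 1L)
  expect_equal(attr(dn, "n_skipped"), 2L)
})

test_that("de novo recovery on a zero-error synthetic trio is exact", {
  cfg <- sim_config(n_sites = 4000, n_denovo = 25, n_genes = 40,
                    chrom_lengths = c(chr1 = 3e5, chr2 = 3e5, chrX = 1e5),
                    seed = 13)
  sim <- simulate_trio(cfg)
  dn <- find_de_novo(sim$trio)
  truth_keys <- sim$truth$sites$key[sim$truth$sites$label == "de_novo"]
  expect_setequal(variant_key(dn), truth_keys)
  # output is disjoint from each parent's alt-carrying site set
  expect_length(intersect(variant_key(dn), variant_key(sim$mother)), 0)
  expect_length(intersect(variant_key(dn), variant_key(sim$father)), 0)
})

test_that("quality filter applies strict MQ and inclusive depth bounds", {
  v <- make_variants(5, mq = c(30, 31, 60, 60, NA),
                     dp = c(50, 50, 10, 9, 50))
  out <- filter_high_confidence(v)
  expect_equal(out$pos, c(200L, 300L))       # mq=30 out, depth 9 out, NA out
  expect_equal(attr(out, "n_missing_quality"), 1L)
  expect_equal(nrow(filter_high_confidence(make_variants(1, dp = 101))), 0L)
  expect_equal(nrow(filter_high_confidence(make_variants(1, dp = 100))), 1L)
})

test_that("rarity filter reduces across sources by maximum and keeps unannotated", {
  v <- make_variants(4,
                     af_dbsnp = c(0.02, NA, 0.005, NA),
                     af_exac = c(NA, NA, 0.02, 0.009))
  out <- filter_rare(v)
  # above threshold in any source excludes; absent everywhere keeps
  expect_equal(out$pos, c(200L, 400L))
  expect_equal(nrow(filter_rare(v, threshold = 0.05)), 4L)
})

test_that("functional filter keeps protein-altering classes only", {
  v <- make_variants(6, csq = c("synonymous", "nonsense", "frameshift",
                                "missense", "splice", "intronic"))
  expect_equal(filter_functional(v)$csq,
               c("nonsense", "frameshift", "missense", "splice"))
  expect_warning(out <- filter_functional(make_variants(1, csq = "weird")),
                 "unknown consequence")
  expect_equal(nrow(out), 0L)
})

test_that("damaging filter requires both tool calls and conservation", {
  v <- make_variants(4,
                     dmg_sift = c("tolerated", "damaging", "damaging", NA),
                     dmg_polyphen = c("tolerated", "tolerated", "damaging", "damaging"),
                     cons = c(3, 3, 1.9, 3))
  out <- filter_damaging(v)
  expect_equal(out$pos, c(200L, 400L))  # conjunction: damaging AND conserved
  expect_equal(filter_damaging(v, min_tools = 2)$pos, integer(0))
})

test_that("filter chain is monotone and the funnel flags violations", {
  cfg <- sim_config(n_sites = 3000, n_denovo = 20, n_genes = 30, seed = 19,
                    chrom_lengths = c(chr1 = 3e5, chr2 = 3e5, chrX = 1e5))
  casc <- denovo_cascade(simulate_trio(cfg)$trio)
  expect_true(all(diff(casc$funnel$count) <= 0))
  keys <- lapply(casc$stages, variant_key)
  for (i in seq_len(length(keys) - 1))
    expect_true(all(keys[[i + 1]] %in% keys[[i]]))
  # final stage equals brute-force predicate application on the de novo set
  dn <- casc$stages$de_novo
  afm <- as.matrix(dn[grep("^af_", names(dn))])
  max_af <- suppressWarnings(apply(afm, 1, max, na.rm = TRUE))
  brute <- dn[dn$mq > 30 & dn$dp >= 10 & dn$dp <= 100 &
                (is.infinite(max_af) | max_af <= 0.01) &
                dn$csq %in% c("missense", "nonsense", "splice", "frameshift") &
                rowSums(as.matrix(dn[grep("^dmg_", names(dn))]) == "damaging",
                        na.rm = TRUE) >= 1 &
                dn$cons >= 2, ]
  expect_setequal(variant_key(casc$stages$damaging), variant_key(brute))
  expect_error(build_funnel(list(a = make_variants(1), b = make_variants(2))),
               "funnel violation")
  empty <- make_variants(1)[0, ]
  expect_equal(build_funnel(list(a = empty, b = empty))$count, c(0L, 0L))
})

test_that("relatedness is genotype concordance over shared sites", {
  a <- make_variants(4, gt = c("0/1", "0/0", "1/1", "0/1"))
  b <- make_variants(4, gt = c("0/1", "0/0", "1/1", "0/1"))
  expect_equal(compute_relatedness(a, b), 1.0)
  b$gt <- c("0/0", "0/1", "0/1", "1/1")
  expect_equal(compute_relatedness(a, b), 0.0)
  expect_error(compute_relatedness(a, make_variants(2, chrom = "chr9")),
               "no jointly genotyped")
})

test_that("trio members are more concordant than unrelated individuals", {
  worse <- vapply(1:20, function(s) {
    cfg <- sim_config(n_sites = 600, n_denovo = 5, n_genes = 20, seed = s,
                      chrom_lengths = c(chr1 = 2e5, chrX = 5e4))
    sim <- simulate_trio(cfg)
    child <- sample_view(sim$trio, "child", carriers_only = FALSE)
    mother <- sample_view(sim$trio, "mother", carriers_only = FALSE)
    unrel <- simulate_unrelated(sim, seed = s + 1000)
    compute_relatedness(child, mother) > compute_relatedness(child, unrel)
  }, logical(1))
  expect_true(all(worse))
})

test_that("inheritance models classify planted fixtures correctly", {
  # sites: 1 de novo het; 2 hom recessive; 3+4 compound het (one from each
  # parent); 5+6 two hets both maternal (cis, not compound); 7 ambiguous
  # origin (both parents carry); 8 hemizygous X
  trio <- make_trio_sites(
    gt_child = c("0/1", "1/1", "0/1", "0/1", "0/1", "0/1", "0/1", "1"),
    gt_mother = c("0/0", "0/1", "0/1", "0/0", "0/1", "0/1", "0/1", "0/1"),
    gt_father = c("0/0", "0/1", "0/0", "0/1", "0/0", "0/0", "0/1", "0"),
    chrom = c(rep("chr1", 3), "chr1", "chr2", "chr2", "chr2", "chrX"),
    gene = c("G1", "G2", "G3", "G3", "G4", "G4", "G4", "G5"),
    child_sex = "male")
  models <- screen_inheritance_models(trio)
  expect_equal(models$de_novo_het$pos, 1000L)
  expect_equal(models$hom_recessive$pos, 2000L)
  expect_setequal(models$comp_het$pos, c(3000L, 4000L))
  expect_equal(attr(models$comp_het, "n_ambiguous"), 1L)
  expect_equal(models$hemizygous$pos, 8000L)
  # cis pair in G4 must not be called compound het
  expect_false(any(models$comp_het$gene == "G4"))
})

test_that("ACMG combination rules reproduce the canonical classifications", {
  expect_equal(acmg_classify(c("PVS1", "PS2", "PM2")), "pathogenic")
  expect_equal(acmg_classify(c("PVS1", "PS2", "PM2", "PP3")), "pathogenic")
  expect_equal(acmg_classify(c("PS2", "PM2", "PP3")), "likely_pathogenic")
  expect_equal(acmg_classify(c("PS2", "PP3")), "uncertain_significance")
  expect_equal(acmg_classify(c("PS1", "PS2")), "pathogenic")
  expect_equal(acmg_classify(c("PM1", "PM2", "PM4")), "likely_pathogenic")
  expect_equal(acmg_classify(c("PVS1", "PM2")), "likely_pathogenic")
  expect_equal(acmg_classify("PP3"), "uncertain_significance")
  expect_error(acmg_classify(c("PS2", "BOGUS")), "BOGUS")
  # purity: repeated evaluation and order invariance
  expect_identical(acmg_classify(c("PM2", "PVS1", "PS2")),
                   acmg_classify(c("PVS1", "PS2", "PM2")))
})

test_that("false de novo rate under genotype error shrinks as QC tightens", {
  fp_counts <- vapply(1:8, function(s) {
    cfg <- sim_config(n_sites = 2000, n_denovo = 0,
                      genotype_error_rate = 0.01, n_genes = 20, seed = s,
                      chrom_lengths = c(chr1 = 2e5, chrX = 5e4),
                      mq_range = c(20, 60), depth_range = c(5L, 60L))
    sim <- simulate_trio(cfg)
    dn <- find_de_novo(sim$trio)
    loose <- nrow(filter_high_confidence(dn, min_mapq = 0, min_depth = 0,
                                         max_depth = 1000))
    tight <- nrow(filter_high_confidence(dn, min_mapq = 55, min_depth = 55,
                                         max_depth = 60))
    c(loose, tight)
  }, numeric(2))
  expect_gt(sum(fp_counts[1, ]), 0)            # errors do create false calls
  expect_lt(sum(fp_counts[2, ]), sum(fp_counts[1, ]))  # tightening removes them
})
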