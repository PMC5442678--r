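make_cohort <- function(label, n, carriers_df, prefix = toupper(label)) {
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  cohort_table(carriers_df, label, ids)
}

test_that("PDS classification is the conjunction of three predicates", {
  v <- make_variants(5,
    csq = c("synonymous", "nonsense", "missense", "missense", "nonsense"),
    af_dbsnp = c(NA, NA, 0.05, NA, NA),
    dmg_sift = c("damaging", "damaging", "damaging", "tolerated", "damaging"),
    dmg_polyphen = "tolerated",
    cons = c(3, 3, 3, 3, 1))
  expect_equal(classify_pds(v), c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # pure function: same input, same answer
  expect_identical(classify_pds(v), classify_pds(v))
})

test_that("burden counts carriers at the individual level", {
  carriers <- data.frame(
    individual = c("CASE0001", "CASE0001", "CASE0002"),
    gene = c("GENE1", "GENE1", "GENE2"),
    variant_key = c("a", "b", "c"), stringsAsFactors = FALSE)
  case <- make_cohort("case", 10, carriers)
  control <- make_cohort("control", 20, carriers[0, ], prefix = "CTRL")
  tab <- gene_burden_table(case, control, genes = c("GENE1", "GENE2", "GENE3"))
  # two PDS in one individual count once
  expect_equal(tab$case_carriers, c(1L, 1L, 0L))
  expect_equal(tab$case_total, rep(10L, 3))
  expect_equal(tab$control_carriers, rep(0L, 3))
  expect_true(all(tab$case_carriers <= tab$case_total))
})

test_that("overlapping individual ids across cohorts are rejected", {
  carriers <- data.frame(individual = "X1", gene = "GENE1",
                         stringsAsFactors = FALSE)
  a <- cohort_table(carriers, "case", c("X1", "X2"))
  b <- cohort_table(carriers, "control", c("X1", "X3"))
  expect_error(gene_burden_table(a, b), "both cohorts")
})

test_that("Fisher exact p matches exhaustive hypergeometric enumeration", {
  # degenerate tables
  expect_equal(fisher_exact_2x2(list(case_carriers = 0, case_total = 100,
                                     control_carriers = 0,
                                     control_total = 100)), 1.0)
  expect_equal(fisher_exact_2x2(list(case_carriers = 5, case_total = 100,
                                     control_carriers = 5,
                                     control_total = 100)), 1.0)
  # the motivating cohort shape: 8 of 2081 vs 0 of 2535
  p_impl <- fisher_exact_2x2(list(case_carriers = 8, case_total = 2081,
                                  control_carriers = 0, control_total = 2535))
  p_oracle <- oracle_fisher_two_sided(8, 2081, 0, 2535)
  expect_lt(abs(p_impl - p_oracle), 1e-9)

  # 200 random tables with margins up to 3000
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(50:3000, 1); n2 <- sample(50:3000, 1)
    a <- rbinom(1, n1, runif(1, 0, 0.05))
    b <- rbinom(1, n2, runif(1, 0, 0.05))
    p1 <- fisher_exact_2x2(list(case_carriers = a, case_total = n1,
                                control_carriers = b, control_total = n2))
    p2 <- oracle_fisher_two_sided(a, n1, b, n2)
    expect_lt(abs(p1 - p2), 1e-9)
  }
  # symmetry under simultaneous cohort swap
  p_sw <- fisher_exact_2x2(list(case_carriers = 0, case_total = 2535,
                                control_carriers = 8, control_total = 2081))
  expect_equal(p_impl, p_sw, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(list(case_carriers = 0, case_total = 0,
                                     control_carriers = 0,
                                     control_total = 10)), "zero-size")
})

test_that("burden scan flags planted enrichment and insufficient data", {
  cfg <- sim_config(n_sites = 10, n_denovo = 0, n_genes = 30,
                    n_case = 800, n_control = 1000,
                    base_carrier_prob = 0.002, enriched_carrier_prob = 0.03,
                    enriched_genes = c("GENE2", "GENE11"), seed = 5)
  sim <- simulate_cohorts(cfg)
  scan <- burden_scan(sim$case, sim$control, c("GENE2", "GENE11", "GENE20"))
  expect_true(all(scan$significant[scan$gene %in% c("GENE2", "GENE11")]))
  expect_false(scan$significant[scan$gene == "GENE20"])

  # all-zero table: insufficient flag, p = 1
  empty <- data.frame(individual = character(), gene = character(),
                      stringsAsFactors = FALSE)
  scan0 <- burden_scan(make_cohort("case", 10, empty),
                       make_cohort("control", 10, empty, prefix = "K"),
                       "GENE1")
  expect_equal(scan0$p, 1)
  expect_true(scan0$insufficient)
  expect_false(scan0$significant)
})

test_that("bootstrap empirical p follows the add-one estimator contract", {
  # every gene with identical burden: observed equals every null replicate
  carriers <- data.frame(
    individual = rep(sprintf("C%03d", 1:5), times = 10),
    gene = rep(paste0("GENE", 1:10), each = 5), stringsAsFactors = FALSE)
  case <- cohort_table(carriers, "case", sprintf("C%03d", 1:50))
  universe <- paste0("GENE", 1:10)
  boot <- bootstrap_gene_sets(case, c("GENE1", "GENE2", "GENE3"), universe,
                              reps = 500, set_size = 3, seed = 4)
  expect_equal(boot$mean$p, 1)
  expect_equal(boot$median$p, 1)
  expect_equal(boot$mean$p,
               (1 + sum(boot$mean$null >= boot$mean$observed)) /
                 (1 + boot$mean$reps))

  # candidate set at the top of the burden distribution is extreme
  carriers2 <- rbind(carriers, data.frame(
    individual = rep(sprintf("C%03d", 6:25), times = 2),
    gene = rep(c("GENE1", "GENE2"), each = 20), stringsAsFactors = FALSE))
  case2 <- cohort_table(carriers2, "case", sprintf("C%03d", 1:50))
  boot2 <- bootstrap_gene_sets(case2, c("GENE1", "GENE2"), universe,
                               reps = 1000, set_size = 2, seed = 4)
  expect_lte(boot2$mean$p, 0.05)
  expect_error(bootstrap_gene_sets(case, "GENE1", universe, set_size = 99),
               "set_size")
})

test_that("bootstrap null is invariant to universe permutation and converges", {
  cfg <- sim_config(n_sites = 10, n_denovo = 0, n_genes = 60, n_case = 500,
                    n_control = 500, base_carrier_prob = 0.01, seed = 6)
  sim <- simulate_cohorts(cfg)
  universe <- gene_universe(cfg)
  b1 <- bootstrap_gene_sets(sim$case, universe[1:6], universe,
                            reps = 400, seed = 9)
  b2 <- bootstrap_gene_sets(sim$case, universe[1:6], rev(universe),
                            reps = 400, seed = 9)
  expect_equal(b1$mean$p, b2$mean$p)

  # law of large numbers: null-sample mean approaches the population mean
  u <- unique(sim$case$carriers[c("individual", "gene")])
  pop_mean <- mean(table(factor(u$gene, levels = universe)))
  b3 <- bootstrap_gene_sets(sim$case, universe[1:6], universe,
                            reps = 10000, seed = 10)
  se <- sd(b3$mean$null) / sqrt(length(b3$mean$null))
  expect_lt(abs(mean(b3$mean$null) - pop_mean), 3 * se)
})

test_that("pathway enrichment matches the hypergeometric tail oracle", {
  universe <- paste0("G", 1:25)
  pathways <- list(PW_hit = paste0("G", 1:6),
                   PW_half = paste0("G", 4:13),
                   PW_miss = paste0("G", 20:25))
  pds <- paste0("G", 1:8)
  res <- pathway_enrichment(pds, pathways, universe, adjust = "BH")
  for (i in seq_len(nrow(res))) {
    k <- res$overlap[i]
    p_oracle <- oracle_hyper_tail(k, res$size[i], length(universe), length(pds))
    expect_equal(res$p[res$pathway == res$pathway[i]][1], p_oracle,
                 tolerance = 1e-12)
  }
  # fully loaded pathway ranks first; zero-overlap pathway has p = 1
  expect_equal(res$pathway[1], "PW_hit")
  expect_equal(res$p[res$pathway == "PW_miss"], 1)
  expect_error(pathway_enrichment(pds, pathways, character()), "universe")
  expect_error(pathway_enrichment(pds, list(), universe), "pathway")
  expect_error(pathway_enrichment(pds, list(A = "NOT_THERE"), universe),
               "outside the universe")
})

test_that("GMT files round-trip", {
  sets <- list(A = c("G1", "G2"), B = c("G3", "G4", "G5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})
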