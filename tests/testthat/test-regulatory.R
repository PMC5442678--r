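reg_fixture <- function() {
  # two TADs on chr1: [0, 5000) and [5000, 10000)
  tads <- data.frame(chrom = "chr1", start0 = c(0, 5000),
                     end0 = c(5000, 10000), tad_id = c("TAD_A", "TAD_B"),
                     stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("GENE1", "GENE2"), chrom = "chr1",
    start0 = c(1000, 6000), end0 = c(2000, 7000), strand = "+",
    stringsAsFactors = FALSE)
  tracks <- list(
    TFBS = data.frame(chrom = "chr1", start0 = 950, end0 = 980,
                      gene_id = NA_character_, stringsAsFactors = FALSE),
    promoter = data.frame(chrom = "chr1", start0 = 900, end0 = 1000,
                          gene_id = "GENE1", stringsAsFactors = FALSE),
    enhancer = data.frame(chrom = "chr1", start0 = c(3000, 8000),
                          end0 = c(3100, 8100), gene_id = NA_character_,
                          stringsAsFactors = FALSE),
    UTR5 = data.frame(chrom = "chr1", start0 = 1000, end0 = 1100,
                      gene_id = "GENE1", stringsAsFactors = FALSE),
    UTR3 = data.frame(chrom = "chr1", start0 = 1900, end0 = 2000,
                      gene_id = "GENE1", stringsAsFactors = FALSE),
    ultrasensitive = data.frame(chrom = "chr1", start0 = 4000, end0 = 4200,
                                gene_id = NA_character_,
                                stringsAsFactors = FALSE))
  list(tads = tads, genes = genes, tracks = tracks)
}

snv_at <- function(pos) {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T", gt = "0/1",
             dp = 50L, mq = 60, stringsAsFactors = FALSE)
}

test_that("high-confidence input selection applies both definitions", {
  snvs <- make_variants(3, mq = c(31, 30, 60), dp = c(10, 50, 101))
  cons <- data.frame(
    consensus_id = c("c1", "c2", "c3"), chrom = "chr1",
    start = c(0L, 100L, 200L), end = c(50L, 150L, 250L), type = "loss",
    n_callers = c(2L, 1L, 3L), callers = "a,b", n_calls = 2L,
    high_confidence = c(TRUE, FALSE, TRUE),
    inheritance = c("de_novo", "de_novo", "maternal"),
    stringsAsFactors = FALSE)
  hc <- select_high_confidence_inputs(snvs, cons)
  expect_equal(hc$snvs$pos, 100L)   # mq 31 depth 10 passes; others fail
  expect_equal(hc$cnvs$consensus_id, "c1")  # >=2 callers AND de novo
})

test_that("track intersection matches a brute-force per-interval scan", {
  fx <- reg_fixture()
  set.seed(5)
  pos <- sample(1:10000, 300)
  snvs <- snv_at(pos)
  ix <- intersect_with_tracks(denovoscreen:::gr_from_point(snvs), fx$tracks)
  for (i in seq_along(pos)) {
    expect_identical(sort(ix$categories[[i]]),
                     oracle_point_categories("chr1", pos[i], fx$tracks))
  }
  # union count: a variant in two categories counts once
  expect_equal(ix$tally$dvprr_total,
               sum(vapply(ix$categories, length, integer(1)) > 0))
})

test_that("promoter/TFBS co-location is tallied as an intersection", {
  fx <- reg_fixture()
  snvs <- snv_at(c(960, 990, 3050))  # in both; promoter only; enhancer only
  ix <- intersect_with_tracks(denovoscreen:::gr_from_point(snvs), fx$tracks)
  expect_setequal(ix$categories[[1]], c("TFBS", "promoter"))
  expect_equal(ix$tally$promoter_TFBS, 1L)
  expect_equal(ix$tally$dvprr_total, 3L)
})

test_that("same_tad requires co-membership and rejects overlapping TADs", {
  fx <- reg_fixture()
  expect_true(same_tad("chr1", 3050, "GENE1", fx$tads, fx$genes))
  expect_false(same_tad("chr1", 3050, "GENE2", fx$tads, fx$genes))
  expect_false(same_tad("chr1", 20000, "GENE1", fx$tads, fx$genes))  # no TAD
  bad <- fx$tads; bad$end0[1] <- 6000
  expect_error(same_tad("chr1", 3050, "GENE1", bad, fx$genes), "overlapping")
  expect_error(same_tad("chr1", 3050, "NOPE", fx$tads, fx$genes), "unknown gene")
})

test_that("DVPRR screen links genes by annotation id, flank and TAD rules", {
  fx <- reg_fixture()
  # promoter of listed gene: link, no TAD requirement
  res <- screen_dvprr(snv_at(990), NULL, fx$tracks, fx$tads, fx$genes,
                      gene_list = "GENE1", list_name = "DDD")
  expect_equal(res$hits$gene, "GENE1")
  expect_true(is.na(res$hits$same_tad))

  # enhancer in the same TAD as the listed gene: link with same_tad = TRUE
  res2 <- screen_dvprr(snv_at(3050), NULL, fx$tracks, fx$tads, fx$genes,
                       gene_list = "GENE1", list_name = "DDD")
  expect_equal(res2$hits$gene, "GENE1")
  expect_true(res2$hits$same_tad)

  # enhancer with the listed gene in the other TAD: no link claimed
  res3 <- screen_dvprr(snv_at(3050), NULL, fx$tracks, fx$tads, fx$genes,
                       gene_list = "GENE2", list_name = "DDD")
  expect_true(is.na(res3$hits$gene))
  expect_equal(res3$funnel$linked, 0L)

  # deletion CNV overlapping a listed gene's annotation: CNV-type hit
  cnv <- data.frame(chrom = "chr1", start = 850L, end = 1200L, type = "loss",
                    stringsAsFactors = FALSE)
  res4 <- screen_dvprr(snv_at(1)[0, ], cnv, fx$tracks, fx$tads, fx$genes,
                       gene_list = "GENE1", list_name = "DDD")
  expect_equal(res4$hits$variant_type, "CNV")
  expect_equal(res4$hits$gene, "GENE1")

  # variant outside all tracks yields no hit
  res5 <- screen_dvprr(snv_at(4900), NULL, fx$tracks, fx$tads, fx$genes,
                       gene_list = "GENE1", list_name = "DDD")
  expect_equal(nrow(res5$hits), 0L)
})

test_that("screen_dvprr is monotone in the flanking distance", {
  fx <- reg_fixture()
  snvs <- snv_at(c(960, 990, 3050, 4100, 8050))
  prev <- -1L
  for (fl in c(0, 1000, 3000, 10000)) {
    res <- screen_dvprr(snvs, NULL, fx$tracks, fx$tads, fx$genes,
                        gene_list = c("GENE1", "GENE2"), flank_bp = fl)
    linked <- res$funnel$linked
    expect_gte(linked, prev)
    prev <- linked
  }
})

test_that("every enhancer/ultrasensitive gene link satisfies the TAD invariant", {
  cfg <- sim_config(n_sites = 2000, n_denovo = 40, n_genes = 40, seed = 31,
                    chrom_lengths = c(chr1 = 2e5, chr2 = 2e5, chrX = 1e5))
  sim <- simulate_trio(cfg)
  ann <- simulate_annotation_tracks(cfg)
  dn <- find_de_novo(sim$trio)
  res <- screen_dvprr(dn, NULL, ann$tracks, ann$tads, ann$genes,
                      ann$gene_lists$DDD, list_name = "DDD")
  hits <- res$hits
  tadreq <- grepl("enhancer|ultrasensitive", hits$categories) & !is.na(hits$gene)
  expect_true(all(hits$same_tad[tadreq]))
  # funnel conservation: union total never exceeds the category sum and
  # equals the brute-force union
  cats <- setdiff(names(res$funnel),
                  c("promoter_TFBS", "dvprr_total", "linked"))
  expect_lte(res$funnel$dvprr_total,
             sum(unlist(res$funnel[cats])))
  brute_union <- sum(vapply(seq_len(nrow(dn)), function(i)
    length(oracle_point_categories(dn$chrom[i], dn$pos[i], ann$tracks)) > 0,
    logical(1)))
  expect_equal(res$funnel$dvprr_total, brute_union)
})

test_that("ncRNA context classification is total with correct precedence", {
  ncrna <- data.frame(
    gene_id = "NC1", chrom = "chr1",
    start0 = c(1000, 2000), end0 = c(1200, 2200), exon = 1:2,
    stringsAsFactors = FALSE)
  # positions: mid-exon, 1 base into intron from exon end, deep intron,
  # outside the gene, terminal 3' span (intronic region near gene end is
  # exon here, so use a wider gene)
  snvs <- snv_at(c(1100, 1202, 1600, 5000, 2100))
  res <- classify_ncrna_context(snvs, ncrna)
  expect_equal(res$contexts[1], "exonic")
  expect_equal(res$contexts[2], "splice_junction")
  expect_equal(res$contexts[3], "intronic")
  expect_true(is.na(res$contexts[4]))
  expect_equal(res$contexts[5], "exonic")
  # exactly one label per ncRNA-overlapping SNV
  inside <- !is.na(res$contexts)
  expect_equal(sum(unlist(res$counts)), sum(inside))
})

test_that("UTR termini of ncRNA bodies are labelled by position", {
  ncrna <- data.frame(
    gene_id = "NC2", chrom = "chr1",
    start0 = c(1000, 5000), end0 = c(1050, 5020), exon = 1:2,
    stringsAsFactors = FALSE)
  res <- classify_ncrna_context(snv_at(c(1080, 4990, 3000)), ncrna)
  expect_equal(res$contexts, c("UTR5", "UTR3", "intronic"))
})
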