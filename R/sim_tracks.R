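TRACK_CATEGORIES <- c("TFBS", "promoter", "enhancer", "UTR5", "UTR3",
                      "ultrasensitive")

#' Simulate regulatory annotation tracks, TAD map, gene models and gene lists
#'
#' Emits the six non-coding annotation categories used by the
#' regulatory-region funnel (TFBS, promoter, enhancer, 5'/3' UTR,
#' ultrasensitive), a map of topologically associating domains (TADs) that
#' tile each chromosome without overlap, protein-coding gene models, ncRNA
#' gene models with exon structure, candidate gene lists (a large
#' disease-gene-screen list and a small hypothesis-driven pathway list), and
#' a GMT-style pathway collection over the gene universe.
#'
#' Promoters are anchored directly upstream of gene starts and carry the
#' gene id, as do UTR intervals; a third of TFBS intervals are placed inside
#' promoters so that the promoter/TFBS intersection tally is exercised.
#' All interval tables are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return A list with `tracks` (named list of interval data frames
#'   `chrom`, `start0`, `end0`, `gene_id`), `tads`, `genes`, `ncrna` (exon
#'   table), `gene_lists` (named list: `DDD`, `UPP`), `pathways` (named list
#'   of member gene vectors).
#' @export
simulate_annotation_tracks <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "tracks"))
  chroms <- names(config$chrom_lengths)
  universe <- gene_universe(config)

  # TADs tile each chromosome exactly
  tads <- do.call(rbind, lapply(chroms, function(cc) {
    len <- config$chrom_lengths[[cc]]
    k <- max(2L, round(len / 1e5))
    breaks <- sort(sample.int(len - 1L, k - 1L))
    data.frame(chrom = cc, start0 = c(0L, breaks), end0 = c(breaks, len),
               stringsAsFactors = FALSE)
  }))
  tads$tad_id <- sprintf("TAD_%03d", seq_len(nrow(tads)))

  glen <- round(10^runif(config$n_genes, 3.5, 4.5))
  gchrom <- sample(chroms, config$n_genes, replace = TRUE,
                   prob = config$chrom_lengths / sum(config$chrom_lengths))
  # gene bodies must fit their chromosome with room for flanking annotation
  glen <- pmin(glen, pmax(500, floor(config$chrom_lengths[gchrom] / 5)),
               config$chrom_lengths[gchrom] - 4001L)
  gstart <- vapply(seq_len(config$n_genes), function(i) {
    sample.int(config$chrom_lengths[[gchrom[i]]] - glen[i] - 4000L, 1L) + 2000L
  }, integer(1))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- data.frame(gene_id = universe, chrom = gchrom, start0 = gstart,
                      end0 = gstart + glen, strand = strand,
                      stringsAsFactors = FALSE)

  prom_len <- 1000L
  promoter <- data.frame(
    chrom = genes$chrom,
    start0 = ifelse(genes$strand == "+", genes$start0 - prom_len, genes$end0),
    end0 = ifelse(genes$strand == "+", genes$start0, genes$end0 + prom_len),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  utr_len <- 300L
  utr5 <- data.frame(
    chrom = genes$chrom,
    start0 = ifelse(genes$strand == "+", genes$start0, genes$end0 - utr_len),
    end0 = ifelse(genes$strand == "+", genes$start0 + utr_len, genes$end0),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  utr3 <- data.frame(
    chrom = genes$chrom,
    start0 = ifelse(genes$strand == "+", genes$end0 - utr_len, genes$start0),
    end0 = ifelse(genes$strand == "+", genes$end0, genes$start0 + utr_len),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)

  rand_track <- function(n, min_len, max_len) {
    cc <- sample(chroms, n, replace = TRUE,
                 prob = config$chrom_lengths / sum(config$chrom_lengths))
    len <- sample(min_len:max_len, n, replace = TRUE)
    s <- vapply(seq_len(n), function(i)
      sample.int(config$chrom_lengths[[cc[i]]] - len[i], 1L) - 1L, integer(1))
    data.frame(chrom = cc, start0 = s, end0 = s + len,
               gene_id = NA_character_, stringsAsFactors = FALSE)
  }

  n_tfbs <- 3L * config$n_genes
  n_in_prom <- round(n_tfbs / 3)
  prom_pick <- sample(nrow(promoter), n_in_prom, replace = TRUE)
  tf_len <- sample(10:30, n_in_prom, replace = TRUE)
  tf_off <- vapply(seq_len(n_in_prom), function(i)
    sample.int(prom_len - tf_len[i], 1L) - 1L, integer(1))
  tfbs_in <- data.frame(chrom = promoter$chrom[prom_pick],
                        start0 = promoter$start0[prom_pick] + tf_off,
                        end0 = promoter$start0[prom_pick] + tf_off + tf_len,
                        gene_id = NA_character_, stringsAsFactors = FALSE)
  tfbs <- rbind(tfbs_in, rand_track(n_tfbs - n_in_prom, 10L, 30L))

  tracks <- list(
    TFBS = tfbs,
    promoter = promoter,
    enhancer = rand_track(config$n_genes, 500L, 2000L),
    UTR5 = utr5,
    UTR3 = utr3,
    ultrasensitive = rand_track(max(3L, round(config$n_genes / 2)), 200L, 600L))

  # ncRNA gene models with exon structure
  n_nc <- max(3L, round(config$n_genes / 4))
  ncrna <- do.call(rbind, lapply(seq_len(n_nc), function(i) {
    cc <- sample(chroms, 1L)
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(80:300, n_ex, replace = TRUE)
    gap <- sample(500:3000, n_ex - 1L, replace = TRUE)
    total <- sum(ex_len) + sum(gap)
    s <- sample.int(config$chrom_lengths[[cc]] - total - 1L, 1L)
    starts <- s + cumsum(c(0L, utils::head(ex_len, -1L) + gap))
    data.frame(gene_id = sprintf("NCRNA%03d", i), chrom = cc,
               start0 = starts, end0 = starts + ex_len,
               exon = seq_len(n_ex), stringsAsFactors = FALSE)
  }))

  gene_lists <- list(
    DDD = sort(sample(universe, max(5L, round(config$n_genes * 0.15)))),
    UPP = sort(sample(universe, max(3L, round(config$n_genes * 0.07)))))

  n_path <- 20L
  pw_min <- min(5L, config$n_genes)
  pw_max <- min(25L, config$n_genes)
  pathways <- stats::setNames(lapply(seq_len(n_path), function(i)
    sort(sample(universe, sample(pw_min:pw_max, 1L)))),
    sprintf("PATH_%02d", seq_len(n_path)))

  list(tracks = tracks, tads = tads, genes = genes, ncrna = ncrna,
       gene_lists = gene_lists, pathways = pathways, config = config)
}
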