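# Independent brute-force oracles used to cross-check the implementation.
# Each is written as a direct transcription of the definition, with no code
# shared with the package internals.

# Two-sided Fisher exact p by exhaustive enumeration of all 2x2 tables with
# the observed margins, summing hypergeometric probabilities no larger than
# the observed table's (with the conventional 1 + 1e-7 relative guard
# against floating-point ties).
oracle_fisher_two_sided <- function(case_carriers, case_total,
                                    control_carriers, control_total) {
  m1 <- case_carriers + control_carriers          # carriers overall
  m2 <- (case_total - case_carriers) + (control_total - control_carriers)
  k <- case_total                                 # draws = case column
  x_all <- max(0, k - m2):min(k, m1)
  probs <- dhyper(x_all, m1, m2, k)
  p_obs <- dhyper(case_carriers, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided hypergeometric enrichment tail by term-by-term enumeration.
oracle_hyper_tail <- function(overlap, pathway_size, universe_size, n_draws) {
  ks <- overlap:min(pathway_size, n_draws)
  sum(vapply(ks, function(i)
    dhyper(i, pathway_size, universe_size - pathway_size, n_draws),
    numeric(1)))
}

# Longest common suffix of two donor-end sequences by direct string
# comparison, longest first.
oracle_common_suffix <- function(a, b) {
  for (k in seq(min(nchar(a), nchar(b)), 1)) {
    if (substring(a, nchar(a) - k + 1) == substring(b, nchar(b) - k + 1))
      return(k)
  }
  0L
}

# Single-linkage consensus clustering by all-pairs adjacency and repeated
# transitive closure on the boolean matrix. Returns a canonical partition:
# a sorted list of sorted member index vectors.
oracle_consensus_partition <- function(calls, ro_threshold = 0.5) {
  n <- nrow(calls)
  ro <- function(i, j) {
    if (calls$chrom[i] != calls$chrom[j]) return(0)
    ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
    if (ov <= 0) return(0)
    min(ov / (calls$end[i] - calls$start[i]),
        ov / (calls$end[j] - calls$start[j]))
  }
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && calls$type[i] == calls$type[j] &&
        ro(i, j) >= ro_threshold) adj[i, j] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  groups <- unique(lapply(seq_len(n), function(i) sort(which(adj[i, ]))))
  groups[order(vapply(groups, min, integer(1)))]
}

canonical_partition <- function(members) {
  groups <- lapply(members, sort)
  groups[order(vapply(groups, min, integer(1)))]
}

# Per-interval brute-force category scan for point variants.
oracle_point_categories <- function(chrom, pos, tracks) {
  cats <- character(0)
  for (cat in names(tracks)) {
    t <- tracks[[cat]]
    for (j in seq_len(nrow(t))) {
      if (t$chrom[j] == chrom && pos - 1 >= t$start0[j] && pos - 1 < t$end0[j]) {
        cats <- c(cats, cat)
        break
      }
    }
  }
  sort(cats)
}

# small trio fixture builder for filter and inheritance-model tests
make_variants <- function(n = 1, ...) {
  base <- data.frame(
    chrom = "chr1", pos = seq_len(n) * 100L, ref = "A", alt = "T",
    gt = "0/1", dp = 50L, mq = 60, csq = "missense", gene = "GENE1",
    af_dbsnp = NA_real_, af_exac = NA_real_,
    dmg_sift = "damaging", dmg_polyphen = "tolerated", cons = 3,
    stringsAsFactors = FALSE)
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

make_trio_sites <- function(gt_child, gt_mother, gt_father,
                            chrom = "chr1", gene = "GENE1",
                            child_sex = "male", csq = "missense") {
  n <- length(gt_child)
  trio <- data.frame(
    chrom = rep_len(chrom, n), pos = seq_len(n) * 1000L,
    ref = "A", alt = "T",
    gt_child = gt_child, gt_mother = gt_mother, gt_father = gt_father,
    dp_child = 50L, dp_mother = 50L, dp_father = 50L,
    mq_child = 60, mq_mother = 60, mq_father = 60,
    csq = rep_len(csq, n), gene = rep_len(gene, n),
    af_dbsnp = NA_real_, dmg_sift = "damaging", cons = 3,
    stringsAsFactors = FALSE)
  attr(trio, "child_sex") <- child_sex
  trio
}
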