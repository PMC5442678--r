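#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the package flows from one top-level seed. Each module
#' draws from its own named substream so that reordering pipeline stages
#' cannot change results. The derived seed is kept below 2^31 - 1.
#'
#' @param seed Integer top-level seed.
#' @param stream Character name of the substream (e.g. `"trio"`, `"cohorts"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131L) %% 1000003L
  as.integer((abs(as.numeric(seed)) + h * 1009) %% 2147483579)
}

# --- genotype helpers ------------------------------------------------------
# Genotypes are strings: diploid "0/0", "0/1", "1/1", missing "./.";
# hemizygous (male X) "0" or "1". Phased separators are normalized on entry.

VALID_GT <- c("0/0", "0/1", "1/0", "1/1", "./.", "0", "1", ".")

gt_normalize <- function(gt) gsub("|", "/", gt, fixed = TRUE)

gt_is_valid <- function(gt) gt_normalize(gt) %in% VALID_GT

#' Does a genotype carry the alternate allele?
#'
#' @param gt Character vector of genotype strings (`"0/1"`, `"1"`, ...).
#' @return Logical vector; `NA` for malformed or missing genotypes.
#' @export
gt_carries_alt <- function(gt) {
  gt <- gt_normalize(gt)
  out <- rep(NA, length(gt))
  known <- gt %in% VALID_GT
  out[known] <- grepl("1", gt[known], fixed = TRUE)
  out[gt %in% c("./.", ".")] <- NA
  out
}

gt_is_het <- function(gt) gt_normalize(gt) %in% c("0/1", "1/0")
gt_is_hom_ref <- function(gt) gt_normalize(gt) %in% c("0/0", "0")
gt_is_hom_alt <- function(gt) gt_normalize(gt) %in% c("1/1", "1")
gt_is_missing <- function(gt) gt_normalize(gt) %in% c("./.", ".")

# Count of alt alleles; hemizygous counts 0/1, missing is NA.
gt_alt_dose <- function(gt) {
  gt <- gt_normalize(gt)
  dose <- rep(NA_integer_, length(gt))
  dose[gt == "0/0"] <- 0L
  dose[gt %in% c("0/1", "1/0")] <- 1L
  dose[gt == "1/1"] <- 2L
  dose[gt == "0"] <- 0L
  dose[gt == "1"] <- 1L
  dose
}

#' Canonical site key for matching variant records
#'
#' `chrom:pos:ref:alt`, used to match records across samples and against
#' truth tables.
#'
#' @param df Variant table with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys.
#' @export
variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

# columns prefixed af_ / dmg_ in a variant table
af_cols <- function(df) grep("^af_", names(df), value = TRUE)
dmg_cols <- function(df) grep("^dmg_", names(df), value = TRUE)

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", ...)
}
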