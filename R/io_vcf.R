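#' Write a per-individual variant table as VCF
#'
#' Emits a minimal VCF 4.2 file with `GT:DP` sample fields and the
#' annotation columns carried as INFO keys: `MQ`, `CSQ_CLASS`, `GENE`,
#' `AF_<source>`, `DMG_<tool>`, `CONS`.
#'
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`, `gt`, `dp`,
#'   `mq`, annotations).
#' @param path Output path.
#' @param sample_id Sample column name.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, sample_id = "SAMPLE") {
  afc <- af_cols(variants); dmc <- dmg_cols(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=CONS,Number=1,Type=Float,Description=\"Conservation score\">",
    vapply(toupper(afc), function(k) sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"Allele frequency\">", k),
      character(1)),
    vapply(toupper(dmc), function(k) sprintf(
      "##INFO=<ID=%s,Number=1,Type=String,Description=\"Damaging call\">", k),
      character(1)),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  info <- vapply(seq_len(nrow(variants)), function(i) {
    kv <- c(sprintf("MQ=%s", variants$mq[i]),
            if (!is.na(variants$csq[i])) sprintf("CSQ_CLASS=%s", variants$csq[i]),
            if (!is.na(variants$gene[i])) sprintf("GENE=%s", variants$gene[i]),
            vapply(afc, function(k) if (is.na(variants[[k]][i])) "" else
              sprintf("%s=%s", toupper(k), variants[[k]][i]), character(1)),
            vapply(dmc, function(k) if (is.na(variants[[k]][i])) "" else
              sprintf("%s=%s", toupper(k), variants[[k]][i]), character(1)),
            if (!is.na(variants$cons[i])) sprintf("CONS=%s", variants$cons[i]))
    paste(kv[nzchar(kv)], collapse = ";")
  }, character(1))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", info, "GT:DP",
                paste(variants$gt, variants$dp, sep = ":"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a variant VCF written by [write_variant_vcf()]
#'
#' Parses with the vcfR package and reconstructs the variant-table layout
#' (`gt`, `dp`, `mq`, `csq`, `gene`, `af_*`, `dmg_*`, `cons`).
#' Multi-allelic records are decomposed to bi-allelic rows (all predicates
#' downstream are allele-level); shared INFO annotations are replicated.
#'
#' @param path VCF path.
#' @return Variant table.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- vcfR::extract.gt(v, element = "DP")
  info_get <- function(key) {
    m <- regmatches(fix$INFO, regexec(paste0("(?:^|;)", key, "=([^;]*)"),
                                      fix$INFO))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  base <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, gt = unname(gt_raw[, 1]),
    dp = as.integer(unname(dp_raw[, 1])),
    mq = as.numeric(info_get("MQ")),
    csq = info_get("CSQ_CLASS"), gene = info_get("GENE"),
    stringsAsFactors = FALSE)
  info_keys <- unique(unlist(regmatches(fix$INFO,
                                        gregexpr("(?:^|;)([A-Z0-9_]+)=",
                                                 fix$INFO))))
  info_keys <- gsub("^;|=$", "", info_keys)
  for (k in grep("^AF_", info_keys, value = TRUE))
    base[[tolower(k)]] <- as.numeric(info_get(k))
  for (k in grep("^DMG_", info_keys, value = TRUE))
    base[[tolower(k)]] <- info_get(k)
  base$cons <- as.numeric(info_get("CONS"))

  multi <- grepl(",", base$alt, fixed = TRUE)
  if (any(multi)) {
    rows <- lapply(seq_len(nrow(base)), function(i) {
      if (!multi[i]) return(base[i, , drop = FALSE])
      alts <- strsplit(base$alt[i], ",", fixed = TRUE)[[1]]
      out <- base[rep(i, length(alts)), , drop = FALSE]
      out$alt <- alts
      # re-express genotypes against each single alt allele
      for (j in seq_along(alts)) {
        g <- gt_normalize(out$gt[j])
        al <- strsplit(g, "/", fixed = TRUE)[[1]]
        al <- ifelse(al == as.character(j), "1", ifelse(al == ".", ".", "0"))
        out$gt[j] <- paste(sort(al), collapse = "/")
      }
      out
    })
    base <- do.call(rbind, rows)
  }
  rownames(base) <- NULL
  base
}

#' Write / read a 4-column pedigree file (child, father, mother, child sex)
#'
#' @param ped List or data frame with `child`, `father`, `mother`,
#'   `child_sex`.
#' @param path File path.
#' @return The pedigree (read) or `path` invisibly (write).
#' @export
write_pedigree <- function(ped, path) {
  write_tsv(as.data.frame(ped[c("child", "father", "mother", "child_sex")],
                          stringsAsFactors = FALSE), path)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) as.list(read_tsv(path)[1, ])

#' Write an interval table as BED (0-based half-open)
#'
#' Optional `gene_id` becomes the BED name column.
#'
#' @param iv Interval table (`chrom`, `start0`, `end0`, optional `gene_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(iv, path) {
  name <- if ("gene_id" %in% names(iv)) ifelse(is.na(iv$gene_id), ".",
                                               iv$gene_id) else "."
  writeLines(paste(iv$chrom, iv$start0, iv$end0, name, sep = "\t"), path)
  invisible(path)
}

#' Read a BED file into a 0-based interval table
#'
#' @param path BED path.
#' @return Interval table (`chrom`, `start0`, `end0`, `gene_id`).
#' @export
read_track_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start0", "end0", "gene_id"),
                          fill = TRUE)
  df$gene_id[df$gene_id %in% c(".", "")] <- NA_character_
  df
}
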