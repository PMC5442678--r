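# GRanges constructors: interval tables are 0-based half-open; SNV tables
# carry 1-based point positions
gr_from_iv <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start0 + 1L, df$end0))
}
gr_from_point <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
}
gr_from_cnv <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Select high-confidence de novo inputs for the regulatory screen
#'
#' High-confidence de novo SNVs are those passing
#' [filter_high_confidence()] (mapping quality strictly above 30, depth in
#' 10-100); high-confidence de novo CNVs are consensus calls supported by
#' two or more callers and labelled `de_novo`.
#'
#' @param denovo_snvs De novo child-view variant table ([find_de_novo()]).
#' @param consensus Consensus CNV table with `inheritance`
#'   ([classify_inheritance()]).
#' @param ... Threshold overrides passed to [filter_high_confidence()].
#' @return List with `snvs` and `cnvs`.
#' @export
select_high_confidence_inputs <- function(denovo_snvs, consensus, ...) {
  snvs <- filter_high_confidence(denovo_snvs, ...)
  cnvs <- consensus[consensus$high_confidence &
                      consensus$inheritance == "de_novo", , drop = FALSE]
  rownames(cnvs) <- NULL
  list(snvs = snvs, cnvs = cnvs)
}

#' Intersect variants with annotation category tracks
#'
#' A point variant hits a category when its position lies inside at least
#' one interval of that track; a CNV hits on any overlap (>= 1 bp): a
#' regulatory element partially deleted is affected. The tally also reports
#' the promoter/TFBS intersection (variants present in both categories).
#'
#' @param gr A [GenomicRanges::GRanges] of variant loci (points for SNVs,
#'   spans for CNVs).
#' @param tracks Named list of category interval tables (`chrom`, `start0`,
#'   `end0`, optional `gene_id`).
#' @return List with `categories` (per-variant character vectors),
#'   `gene_links` (per-variant named list category -> linked gene ids) and
#'   `tally` (per-category hit counts, `promoter_TFBS`, and `dvprr_total`,
#'   the size of the union across categories).
#' @export
intersect_with_tracks <- function(gr, tracks) {
  n <- length(gr)
  categories <- rep(list(character(0)), n)
  gene_links <- rep(list(list()), n)
  for (cat in names(tracks)) {
    track <- tracks[[cat]]
    if (nrow(track) == 0L) next
    hits <- GenomicRanges::findOverlaps(gr, gr_from_iv(track))
    for (k in seq_along(hits)) {
      i <- S4Vectors::queryHits(hits)[k]
      j <- S4Vectors::subjectHits(hits)[k]
      if (!(cat %in% categories[[i]]))
        categories[[i]] <- c(categories[[i]], cat)
      gid <- track$gene_id[j]
      if (!is.null(gid) && !is.na(gid))
        gene_links[[i]][[cat]] <- unique(c(gene_links[[i]][[cat]], gid))
    }
  }
  counts <- vapply(names(tracks), function(cat)
    sum(vapply(categories, function(x) cat %in% x, logical(1))), integer(1))
  tally <- as.list(counts)
  tally$promoter_TFBS <- sum(vapply(categories, function(x)
    all(c("promoter", "TFBS") %in% x), logical(1)))
  tally$dvprr_total <- sum(lengths(categories) > 0L)
  list(categories = categories, gene_links = gene_links, tally = tally)
}

#' Are a variant locus and a gene in the same topological domain?
#'
#' TRUE only when the variant position and the gene-body midpoint fall in
#' the same TAD interval; a locus covered by no TAD fails (co-localization
#' is never claimed without evidence). Overlapping TADs are an input error.
#'
#' @param chrom,pos Variant locus (1-based position; for a CNV use a
#'   breakpoint or midpoint).
#' @param gene_id Gene to test.
#' @param tads TAD interval table (`chrom`, `start0`, `end0`).
#' @param genes Gene-model table (`gene_id`, `chrom`, `start0`, `end0`).
#' @return Logical.
#' @export
same_tad <- function(chrom, pos, gene_id, tads, genes) {
  check_tads_disjoint(tads)
  g <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene id: ", gene_id, call. = FALSE)
  tad_of <- function(cc, p1) {
    hit <- which(tads$chrom == cc & tads$start0 < p1 & p1 <= tads$end0)
    if (length(hit) == 0L) NA_character_ else tads$tad_id[hit[1]]
  }
  mid1 <- floor((g$start0[1] + g$end0[1]) / 2) + 1L
  tv <- tad_of(chrom, pos)
  tg <- tad_of(g$chrom[1], mid1)
  !is.na(tv) && !is.na(tg) && tv == tg
}

check_tads_disjoint <- function(tads) {
  for (cc in unique(tads$chrom)) {
    t <- tads[tads$chrom == cc, , drop = FALSE]
    t <- t[order(t$start0), , drop = FALSE]
    if (nrow(t) > 1L && any(t$start0[-1L] < t$end0[-nrow(t)]))
      stop("overlapping TADs on ", cc, call. = FALSE)
  }
  invisible(TRUE)
}

#' Screen de novo variants in possible regulatory regions (DVPRR)
#'
#' Runs the regulatory-region funnel for one candidate gene list: variants
#' hitting at least one annotation category are DVPRRs; a candidate-gene
#' link is claimed when the variant lies inside a listed gene's own
#' regulatory annotation (promoter/UTR intervals carrying the gene id) or
#' within `flank_bp` of the listed gene body. Whenever the variant's
#' categories include enhancer or ultrasensitive regions, any claimed link
#' additionally requires variant and gene to share a topological domain.
#'
#' @param snvs High-confidence de novo SNV table (1-based `pos`).
#' @param cnvs High-confidence de novo consensus CNV table (0-based
#'   `start`/`end`); may be `NULL` or empty.
#' @param tracks,tads,genes Annotation inputs (see
#'   [simulate_annotation_tracks()]).
#' @param gene_list Character vector of candidate gene ids.
#' @param list_name Label recorded on each hit (e.g. `"DDD"`, `"UPP"`).
#' @param flank_bp Flanking distance for gene-body proximity links
#'   (default 10000).
#' @return List with `hits` (data frame: `variant`, `variant_type`,
#'   `categories`, `gene`, `source_list`, `same_tad`) and `funnel`
#'   (category tallies, `dvprr_total`, `linked`).
#' @export
screen_dvprr <- function(snvs, cnvs, tracks, tads, genes, gene_list,
                         list_name = "custom", flank_bp = 10000) {
  stopifnot(length(gene_list) > 0L)
  listed <- genes[genes$gene_id %in% gene_list, , drop = FALSE]

  screen_one <- function(gr, keys, type) {
    if (length(gr) == 0L)
      return(list(hits = NULL,
                  tally = stats::setNames(as.list(rep(0L, length(tracks) + 2L)),
                                          c(names(tracks), "promoter_TFBS",
                                            "dvprr_total"))))
    ix <- intersect_with_tracks(gr, tracks)
    dist_to_listed <- if (nrow(listed)) {
      d <- matrix(Inf, length(gr), nrow(listed))
      gl <- gr_from_iv(listed)
      for (j in seq_len(nrow(listed))) {
        dd <- suppressWarnings(GenomicRanges::distance(
          gr, rep(gl[j], length(gr))))
        d[, j] <- ifelse(is.na(dd), Inf, dd)
      }
      d
    } else matrix(Inf, length(gr), 0L)
    rows <- lapply(which(lengths(ix$categories) > 0L), function(i) {
      cats <- ix$categories[[i]]
      tad_req <- any(cats %in% c("enhancer", "ultrasensitive"))
      pos1 <- GenomicRanges::start(gr)[i]
      cc <- as.character(GenomicRanges::seqnames(gr))[i]
      ok_tad <- function(g) !tad_req || same_tad(cc, pos1, g, tads, genes)
      # track-id links first (a listed gene's own promoter/UTR), then
      # gene-body proximity within flank_bp
      link <- NA_character_
      track_genes <- intersect(unique(unlist(ix$gene_links[[i]])), gene_list)
      for (g in track_genes) if (ok_tad(g)) { link <- g; break }
      if (is.na(link) && nrow(listed)) {
        near <- which(dist_to_listed[i, ] <= flank_bp)
        near <- near[order(dist_to_listed[i, near])]
        for (j in near) if (ok_tad(listed$gene_id[j])) {
          link <- listed$gene_id[j]; break
        }
      }
      data.frame(variant = keys[i], variant_type = type,
                 categories = paste(sort(cats), collapse = ","),
                 gene = link, source_list = list_name,
                 same_tad = if (tad_req && !is.na(link)) TRUE else NA,
                 stringsAsFactors = FALSE)
    })
    list(hits = if (length(rows)) do.call(rbind, rows) else NULL,
         tally = ix$tally)
  }

  res_snv <- screen_one(gr_from_point(snvs), variant_key(snvs), "SNV")
  res_cnv <- if (!is.null(cnvs) && nrow(cnvs) > 0L) {
    screen_one(gr_from_cnv(cnvs),
               paste(cnvs$chrom, cnvs$start, cnvs$end, cnvs$type, sep = ":"),
               "CNV")
  } else list(hits = NULL, tally = NULL)

  hits <- rbind(res_snv$hits, res_cnv$hits)
  if (is.null(hits))
    hits <- data.frame(variant = character(), variant_type = character(),
                       categories = character(), gene = character(),
                       source_list = character(), same_tad = logical(),
                       stringsAsFactors = FALSE)
  tally <- res_snv$tally
  if (!is.null(res_cnv$tally))
    for (nm in names(tally)) tally[[nm]] <- tally[[nm]] + res_cnv$tally[[nm]]
  tally$linked <- sum(!is.na(hits$gene))
  list(hits = hits, funnel = tally)
}
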