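ACMG_CODES <- c("PVS1",
                paste0("PS", 1:4),
                paste0("PM", 1:6),
                paste0("PP", 1:5))

#' Combine ACMG evidence codes into a five-tier classification
#'
#' Applies the standard ACMG/AMP combining rules for pathogenic-side
#' evidence (very strong PVS1, strong PS1-PS4, moderate PM1-PM6, supporting
#' PP1-PP5):
#'
#' * Pathogenic: PVS1 with (>=1 PS, or >=2 PM, or 1 PM + 1 PP, or >=2 PP);
#'   or >=2 PS; or 1 PS with (>=3 PM, or 2 PM + >=2 PP, or 1 PM + >=4 PP).
#' * Likely pathogenic: PVS1 + 1 PM; or 1 PS + 1-2 PM; or 1 PS + >=2 PP;
#'   or >=3 PM; or 2 PM + >=2 PP; or 1 PM + >=4 PP.
#' * Otherwise: uncertain significance (benign-side codes are out of scope
#'   for a de novo candidate screen).
#'
#' The function is pure and deterministic: the same code set always yields
#' the same classification.
#'
#' @param codes Character vector of evidence codes, e.g.
#'   `c("PVS1", "PS2", "PM2")`.
#' @return One of `"pathogenic"`, `"likely_pathogenic"`,
#'   `"uncertain_significance"`.
#' @export
acmg_classify <- function(codes) {
  codes <- unique(toupper(codes))
  unknown <- setdiff(codes, ACMG_CODES)
  if (length(unknown))
    stop("unknown ACMG evidence code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pvs <- sum(codes == "PVS1")
  ps <- sum(grepl("^PS", codes))
  pm <- sum(grepl("^PM", codes))
  pp <- sum(grepl("^PP", codes))

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  if (pathogenic) return("pathogenic")

  likely <-
    (pvs >= 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  if (likely) return("likely_pathogenic")

  "uncertain_significance"
}
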