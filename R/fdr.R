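# Target-decoy false-discovery-rate control.
#
# Estimator: FDR(s) = #decoy(score >= s) / #target(score >= s), the plain
# D/T form. The cutoff is the smallest observed score s with FDR(s) below
# the threshold; ties at the cutoff are accepted.

fdr_cutoff <- function(score, is_decoy, fdr_threshold) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; d <- is_decoy[ord]
  cum_d <- cumsum(d)
  cum_t <- cumsum(!d)
  # evaluate FDR at each distinct score, counting all rows with score >= s
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  fdr <- ifelse(cum_t == 0L, Inf, cum_d / cum_t)
  ok <- which(last_of_tie & fdr < fdr_threshold)
  if (!length(ok))
    stop("no identifications at requested FDR ", fdr_threshold)
  s[max(ok)]   # smallest score still under threshold
}

#' Filter PSMs at a target-decoy FDR threshold
#'
#' Scores are pooled over targets and decoys; the accepted set is all target
#' rows with `score >= cutoff`, where the cutoff is the smallest observed
#' score whose running decoy/target ratio stays below `fdr_threshold`.
#' Decoy rows are removed from the accepted set.
#'
#' @param psms `data.table` with at least `score` and `is_decoy` (logical)
#' @param fdr_threshold proportion in (0,1); default 0.01
#' @return list: `accepted` (target rows passing), `cutoff` (score)
#' @export
fdr_filter <- function(psms, fdr_threshold = 0.01) {
  psms <- data.table::as.data.table(psms)
  stopifnot(all(c("score", "is_decoy") %in% names(psms)))
  cutoff <- fdr_cutoff(psms$score, psms$is_decoy, fdr_threshold)
  list(accepted = psms[psms$score >= cutoff & !psms$is_decoy],
       cutoff = cutoff)
}

#' Protein-level FDR on best-peptide scores
#'
#' Repeats the target-decoy procedure at the protein level: each protein
#' (target or DECOY_) is scored by its best supporting peptide score, and the
#' same D/T cutoff rule is applied.
#'
#' @param protein_scores `data.table` with `protein_id`, `best_score`,
#'   `is_decoy`
#' @param fdr_threshold proportion in (0,1)
#' @return list: `accepted_ids` (target protein ids passing), `cutoff`
#' @export
protein_fdr_filter <- function(protein_scores, fdr_threshold = 0.01) {
  ps <- data.table::as.data.table(protein_scores)
  cutoff <- fdr_cutoff(ps$best_score, ps$is_decoy, fdr_threshold)
  list(accepted_ids = ps$protein_id[ps$best_score >= cutoff & !ps$is_decoy],
       cutoff = cutoff)
}
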