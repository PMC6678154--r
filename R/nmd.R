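# Nonsense-mediated decay classification by the 50-nt last-junction rule:
# a stop codon ending at least `threshold_nt` nucleotides upstream of the
# last exon-exon junction (in mature-mRNA space) flags the transcript as an
# NMD target. Single-exon transcripts have no junction and are never NMD.

#' Classify one transcript/ORF pair for NMD targeting
#'
#' Distances are measured in mature-mRNA (0-based half-open) space from the
#' base after the stop codon (`stop_nt`, exclusive end) to the position of
#' the last exon-exon junction, `d = last_junction_pos - stop_nt`. The
#' boundary `d == threshold_nt` is classified NMD (the rule is "at least").
#'
#' @param model a `transcript_model`
#' @param orf one row of an ORF table (list/data.frame with `orf_id`,
#'   `start_nt`, `stop_nt`, `has_stop`)
#' @param threshold_nt rule-of-thumb distance, default 50
#' @return one-row `data.table`: transcript_id, orf_id, n_exons,
#'   last_junction_pos, stop_end, d, is_nmd
#' @export
classify_nmd <- function(model, orf, threshold_nt = 50L) {
  widths <- model$exons[, "end"] - model$exons[, "start"] + 1L
  total <- sum(widths)
  if (orf$stop_nt > total || orf$start_nt < 0L)
    stop("ORF ", orf$orf_id, " exceeds spliced length of ",
         model$transcript_id, " (inconsistent inputs)")
  n_exons <- length(widths)
  last_junction <- if (n_exons >= 2L) sum(widths[-n_exons]) else NA_integer_
  d <- if (n_exons >= 2L) last_junction - orf$stop_nt else NA_integer_
  is_nmd <- n_exons >= 2L && isTRUE(orf$has_stop) && !is.na(d) &&
    d >= threshold_nt
  data.table::data.table(
    transcript_id = model$transcript_id, orf_id = orf$orf_id,
    n_exons = n_exons, last_junction_pos = last_junction,
    stop_end = orf$stop_nt, d = d, is_nmd = is_nmd)
}

#' Classify a set of transcripts against their ORFs
#'
#' For each transcript with at least one ORF, the longest ORF (first row per
#' transcript in [find_orfs()] order) is classified.
#'
#' @param models named list of `transcript_model`
#' @param orf_table ORF table from [translate_database()]
#' @param threshold_nt default 50
#' @return `data.table` of NMD calls (one per transcript with an ORF)
#' @export
classify_nmd_set <- function(models, orf_table, threshold_nt = 50L) {
  ot <- data.table::as.data.table(orf_table)
  first <- ot[, .SD[1L], by = "transcript_id"]
  calls <- lapply(seq_len(nrow(first)), function(i) {
    m <- models[[first$transcript_id[i]]]
    if (is.null(m)) stop("no transcript model for ", first$transcript_id[i])
    classify_nmd(m, first[i], threshold_nt = threshold_nt)
  })
  data.table::rbindlist(calls)
}

#' NMD composition of a transcript set
#'
#' @param calls `data.table` from [classify_nmd_set()] (needs `transcript_id`,
#'   `is_nmd`)
#' @param subset optional character vector of transcript ids to restrict to
#' @return list: `n_nmd`, `n_total`, `percent` (1 decimal, round-half-up)
#' @export
nmd_composition <- function(calls, subset = NULL) {
  calls <- data.table::as.data.table(calls)
  if (!is.null(subset)) calls <- calls[calls$transcript_id %in% subset]
  if (nrow(calls) == 0L) stop("empty transcript set in nmd_composition")
  n_nmd <- sum(calls$is_nmd)
  list(n_nmd = n_nmd, n_total = nrow(calls),
       percent = percent_of(n_nmd, nrow(calls), digits = 1L))
}
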