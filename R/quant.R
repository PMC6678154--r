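# NSAF label-free quantification and two-sample differential expression.
#
# NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j), per sample; a length-corrected
# relative abundance that sums to 1 over quantified proteins.

#' Normalized spectral abundance factors for one sample
#'
#' @param spc integer vector of spectral counts in the sample (0 allowed)
#' @param length_aa protein lengths L in residues (all > 0)
#' @return list: `saf` = SpC/L, `nsaf` = saf / sum(saf)
#' @export
nsaf <- function(spc, length_aa) {
  if (any(length_aa <= 0)) stop("protein length must be positive")
  if (all(spc == 0)) stop("nothing quantified in sample (all SpC zero)")
  saf <- spc / length_aa
  list(saf = saf, nsaf = saf / sum(saf))
}

#' Build the two-sample quantification table
#'
#' Computes SAF and NSAF per sample over the validated protein groups, the
#' pseudocounted log2 fold change, and the differential-expression call.
#' The pseudocount (+0.5 SpC, both samples, fold-change computation only)
#' makes sample-specific proteins comparable; reported `nsaf_*` columns are
#' pseudocount-free.
#'
#' @param groups validated protein groups ([infer_proteins()] output with
#'   `validated == TRUE` rows)
#' @param sample_a,sample_b sample identifiers (fold change is B over A)
#' @param min_peptides per-sample distinct-peptide requirement; proteins
#'   meeting it in neither sample are `not_quantifiable`
#' @param up_fc,down_fc fold-change thresholds (boundary inclusive)
#' @return `data.table`: protein_id, gene_id, source, length_aa, spc_a, spc_b,
#'   npep_a, npep_b, saf_a/b, nsaf_a/b, fc, log2fc, call
#' @export
quantify_proteins <- function(groups, sample_a, sample_b, min_peptides = 2L,
                              up_fc = 4, down_fc = 0.25) {
  g <- data.table::as.data.table(groups)
  g <- g[g$validated == TRUE]
  if (nrow(g) == 0L) stop("no validated proteins to quantify")
  pull <- function(col, nm) vapply(g[[col]], function(x)
    if (!is.null(x[[nm]])) as.numeric(x[[nm]]) else 0, numeric(1L))
  spc_a <- pull("spc_per_sample", sample_a)
  spc_b <- pull("spc_per_sample", sample_b)
  npep_a <- pull("npep_per_sample", sample_a)
  npep_b <- pull("npep_per_sample", sample_b)
  qa <- nsaf(spc_a, g$length_aa)
  qb <- nsaf(spc_b, g$length_aa)
  # pseudocounted NSAF used only for the ratio
  pa <- (spc_a + 0.5) / g$length_aa
  pb <- (spc_b + 0.5) / g$length_aa
  fc <- (pb / sum(pb)) / (pa / sum(pa))
  quantifiable <- npep_a >= min_peptides | npep_b >= min_peptides
  call <- ifelse(!quantifiable, "not_quantifiable",
          ifelse(fc >= up_fc, "up",
          ifelse(fc <= down_fc, "down", "unchanged")))
  data.table::data.table(
    protein_id = g$protein_id, gene_id = g$gene_id, source = g$source,
    length_aa = g$length_aa, spc_a = spc_a, spc_b = spc_b,
    npep_a = as.integer(npep_a), npep_b = as.integer(npep_b),
    saf_a = qa$saf, saf_b = qb$saf, nsaf_a = qa$nsaf, nsaf_b = qb$nsaf,
    fc = fc, log2fc = log2(fc), call = call)
}

#' Differential-expression calls from a quantification table
#'
#' Re-derives calls at given thresholds and summarizes them. Fold-change
#' boundaries are inclusive (`fc >= up_fc` is up, `fc <= down_fc` is down).
#'
#' @param quant output of [quantify_proteins()]
#' @param up_fc,down_fc thresholds (defaults 4 and 0.25)
#' @return list: `table` (quant with refreshed `call`), `n_up`, `n_down`,
#'   `n_total_de`, `n_quantified`
#' @export
differential <- function(quant, up_fc = 4, down_fc = 0.25) {
  q <- data.table::as.data.table(quant)
  quantifiable <- q$call != "not_quantifiable"
  q$call <- ifelse(!quantifiable, "not_quantifiable",
            ifelse(q$fc >= up_fc, "up",
            ifelse(q$fc <= down_fc, "down", "unchanged")))
  n_up <- sum(q$call == "up")
  n_down <- sum(q$call == "down")
  list(table = q, n_up = n_up, n_down = n_down, n_total_de = n_up + n_down,
       n_quantified = sum(quantifiable))
}

#' Between-sample correlation of NSAF profiles
#'
#' Pearson correlation of log10(NSAF) over proteins quantified (nonzero) in
#' both samples; Spearman available for robustness checks.
#'
#' @param nsaf_a,nsaf_b per-protein NSAF vectors for the two samples
#' @param method `"pearson"` (log10-transformed) or `"spearman"` (ranks)
#' @return correlation coefficient
#' @export
sample_correlation <- function(nsaf_a, nsaf_b, method = c("pearson",
                                                          "spearman")) {
  method <- match.arg(method)
  keep <- nsaf_a > 0 & nsaf_b > 0
  if (sum(keep) < 3L)
    stop("fewer than 3 proteins quantified in both samples")
  if (method == "pearson")
    cor(log10(nsaf_a[keep]), log10(nsaf_b[keep]), method = "pearson")
  else
    cor(nsaf_a[keep], nsaf_b[keep], method = "spearman")
}
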