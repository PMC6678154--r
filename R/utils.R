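#' @importFrom stats rnorm rpois rlnorm rbinom rnbinom rmultinom rexp runif
#'   setNames phyper p.adjust cor median quantile
#' @importFrom utils head tail
#' @importFrom methods is
#' @import data.table
NULL

# package code uses data.table indexing semantics
.datatable.aware <- TRUE

# Coordinate conventions, used everywhere:
#   * genomic coordinates are 1-based, closed (GFF3)
#   * mature-mRNA (spliced) coordinates are 0-based, half-open
# Every conversion between the two goes through the two helpers below so the
# off-by-one risk lives in exactly one place.

#' Convert a genomic interval to mature-mRNA coordinates
#'
#' Maps a 1-based closed genomic interval lying inside one exon of a
#' transcript model to the transcript's 0-based half-open spliced coordinate
#' system (5' to 3' in transcript orientation).
#'
#' @param model a `transcript_model`
#' @param gstart,gend 1-based closed genomic interval, `gstart <= gend`
#' @return integer vector `c(start, end)`, 0-based half-open mRNA coordinates
#' @export
genomic_to_mrna <- function(model, gstart, gend) {
  stopifnot(gstart <= gend)
  ex <- model$exons                      # ordered 5'->3' in transcript space
  widths <- ex[, "end"] - ex[, "start"] + 1L
  offs <- c(0L, cumsum(widths))          # mRNA offset of each exon start
  hit <- which(ex[, "start"] <= gstart & ex[, "end"] >= gend)
  if (length(hit) != 1L)
    stop("interval [", gstart, ",", gend, "] does not lie within one exon of ",
         model$transcript_id)
  if (model$strand == "+") {
    m0 <- unname(offs[hit] + (gstart - ex[hit, "start"]))
    c(m0, m0 + (gend - gstart + 1L))
  } else {
    m0 <- unname(offs[hit] + (ex[hit, "end"] - gend))
    c(m0, m0 + (gend - gstart + 1L))
  }
}

#' Convert a mature-mRNA interval back to genomic coordinates
#'
#' Inverse of [genomic_to_mrna()] for intervals within a single exon.
#'
#' @param model a `transcript_model`
#' @param mstart,mend 0-based half-open mRNA interval
#' @return integer vector `c(start, end)`, 1-based closed genomic coordinates
#' @export
mrna_to_genomic <- function(model, mstart, mend) {
  stopifnot(mstart < mend)
  ex <- model$exons
  widths <- ex[, "end"] - ex[, "start"] + 1L
  offs <- c(0L, cumsum(widths))
  hit <- which(offs[-length(offs)] <= mstart & offs[-1L] >= mend)
  if (length(hit) < 1L)
    stop("mRNA interval [", mstart, ",", mend, ") spans an exon junction of ",
         model$transcript_id)
  hit <- hit[1L]
  if (model$strand == "+") {
    g1 <- unname(ex[hit, "start"] + (mstart - offs[hit]))
    c(g1, g1 + (mend - mstart) - 1L)
  } else {
    g2 <- unname(ex[hit, "end"] - (mstart - offs[hit]))
    c(g2 - (mend - mstart) + 1L, g2)
  }
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; report percentages use the
#' conventional round-half-up instead (22.25 -> 22.3).
#'
#' @param x numeric
#' @param digits number of decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent of a whole, rounded per the reporting convention
#'
#' @param part,whole counts
#' @param digits decimal places (0 for overlap shares, 1 for compositions,
#'   2 where two decimals are conventional)
#' @return numeric percent
#' @export
percent_of <- function(part, whole, digits = 1L) {
  if (whole <= 0) stop("percent_of: whole must be positive")
  round_half_up(100 * part / whole, digits)
}

VALID_NT <- c("A", "C", "G", "T", "N")

assert_nucleotides <- function(seqs, where = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGTN]", "", seqs[bad][1L]), "")))
    stop("invalid nucleotide character(s) ", paste(chars, collapse = ","),
         " in ", where, " (alphabet is ACGTN, uppercase)")
  }
  invisible(TRUE)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq string over ACGTN
#' @return reverse complement, uppercase
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# standard nuclear code; codons containing N translate to X
.codon_table <- local({
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- chartr("U", "T", names(tab))
  tab
})

#' Translate a nucleotide string (standard code)
#'
#' Translates complete codons from position 1; a trailing partial codon is
#' dropped. Codons containing N become `X`. Stop codons translate to `*`.
#'
#' @param seq nucleotide string over ACGTN
#' @return amino-acid string
#' @export
translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# I and L are isobaric and indistinguishable by mass spectrometry
il_collapse <- function(x) chartr("I", "L", x)
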