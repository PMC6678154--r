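# In-silico proteolysis and decoy construction.

#' In-silico tryptic digestion
#'
#' Cleaves after K or R, suppressed when the next residue is P (the field's
#' default trypsin rule; set `suppress_proline = FALSE` for strict K/R
#' cleavage). Emits all products with 0..`missed_cleavages` internal missed
#' sites, including protein N- and C-terminal peptides, filtered to
#' `[min_len, max_len]` residues. Case-insensitive in the input.
#'
#' @param protein_seq amino-acid string
#' @param missed_cleavages maximum internal missed cleavage sites (default 2)
#' @param min_len,max_len peptide length bounds in residues (default 7..50,
#'   a typical LC-MS/MS detectability window)
#' @param suppress_proline apply the KP/RP no-cleavage rule (default TRUE)
#' @return character vector of unique peptides (sorted)
#' @export
digest <- function(protein_seq, missed_cleavages = 2L, min_len = 7L,
                   max_len = 50L, suppress_proline = TRUE) {
  stopifnot(missed_cleavages >= 0L, min_len >= 1L, max_len >= min_len)
  protein_seq <- toupper(protein_seq)
  n <- nchar(protein_seq)
  if (n == 0L) return(character())
  res <- strsplit(protein_seq, "")[[1L]]
  cut_after <- res %in% c("K", "R")
  if (suppress_proline && n > 1L)
    cut_after[1:(n - 1L)] <- cut_after[1:(n - 1L)] & res[2:n] != "P"
  cut_after[n] <- FALSE
  bounds <- c(0L, which(cut_after), n)   # fragment boundaries, 0-based cuts
  nb <- length(bounds)
  peps <- character()
  for (i in 1:(nb - 1L)) {
    jmax <- min(i + 1L + missed_cleavages, nb)
    for (j in (i + 1L):jmax) {
      len <- bounds[j] - bounds[i]
      if (len >= min_len && len <= max_len)
        peps <- c(peps, substr(protein_seq, bounds[i] + 1L, bounds[j]))
    }
  }
  sort(unique(peps))
}

#' Build a concatenated target + reversed-decoy protein database
#'
#' Appends each protein's reversed sequence under the id `DECOY_<id>`; the
#' result has exactly twice as many entries as the input.
#'
#' @param proteins named character vector of target proteins
#' @return named character vector: targets followed by decoys
#' @export
reverse_decoy <- function(proteins) {
  ids <- names(proteins)
  if (any(startsWith(ids, "DECOY_")))
    stop("input already contains DECOY_-prefixed ids: ",
         ids[startsWith(ids, "DECOY_")][1L])
  rev_one <- function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  decoys <- vapply(proteins, rev_one, character(1L))
  names(decoys) <- paste0("DECOY_", ids)
  c(proteins, decoys)
}
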