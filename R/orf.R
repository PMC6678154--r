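# ORF extraction from oriented transcript sequences (forward strand, three
# frames). The role TransDecoder-like tools play upstream of peptide matching,
# reduced to the part the analysis needs: ATG-initiated ORFs, longest per stop.

#' Find open reading frames in a transcript sequence
#'
#' Scans the forward strand in all three frames for ATG-initiated ORFs, each
#' extended to the first in-frame stop codon or to the transcript end
#' (`has_stop = FALSE` if none). Nested ORFs sharing a stop are reduced to the
#' longest (most 5' ATG). Codons containing N translate to `X`; `X` never
#' terminates an ORF.
#'
#' `start_nt` / `stop_nt` are 0-based half-open mRNA coordinates; `stop_nt`
#' is exclusive of nothing — it points one past the last base of the stop
#' codon (or of the last complete codon when `has_stop = FALSE`).
#'
#' @param seq nucleotide string over ACGTN (uppercase)
#' @param min_aa minimum protein length in residues (stop excluded)
#' @param require_atg if `FALSE`, also report 5'-partial ORFs that begin at
#'   the first codon of a frame with no upstream ATG (off by default)
#' @return `data.table` with columns `orf_id` (empty, filled by callers),
#'   `frame`, `start_nt`, `stop_nt`, `protein_seq`, `has_stop`, `length_aa`,
#'   sorted by `length_aa` descending then `start_nt` ascending
#' @export
find_orfs <- function(seq, min_aa = 100L, require_atg = TRUE) {
  stopifnot(min_aa >= 1L)
  empty <- data.table::data.table(
    orf_id = character(), frame = integer(), start_nt = integer(),
    stop_nt = integer(), protein_seq = character(), has_stop = logical(),
    length_aa = integer())
  if (is.na(seq) || nchar(seq) < 3L) return(empty)
  assert_nucleotides(seq, "find_orfs input")
  out <- list()
  for (frame in 0:2) {
    n_codon <- (nchar(seq) - frame) %/% 3L
    if (n_codon < 1L) next
    starts0 <- frame + 3L * (seq_len(n_codon) - 1L)       # 0-based codon starts
    codons <- substring(seq, starts0 + 1L, starts0 + 3L)
    is_start <- codons == "ATG"
    is_stop <- is_stop_codon(codons)
    if (!any(is_start) && require_atg) next
    # segment index: codons between consecutive stops share a segment
    seg <- cumsum(c(0L, head(as.integer(is_stop), -1L)))
    starts_by_seg <- split(which(is_start), seg[is_start])
    stop_by_seg <- split(which(is_stop), seg[is_stop])    # at most 1 per seg
    for (s in names(starts_by_seg)) {
      first_atg <- starts_by_seg[[s]][1L]                  # most 5' ATG
      stop_i <- stop_by_seg[[s]]
      has_stop <- length(stop_i) == 1L
      end_codon <- if (has_stop) stop_i else n_codon
      len_aa <- end_codon - first_atg + if (has_stop) 0L else 1L
      if (len_aa < min_aa) next
      aa_end <- if (has_stop) end_codon - 1L else end_codon
      prot <- paste(ifelse(grepl("N", codons[first_atg:aa_end], fixed = TRUE),
                           "X", .codon_table[codons[first_atg:aa_end]]),
                    collapse = "")
      out[[length(out) + 1L]] <- data.table::data.table(
        orf_id = "", frame = frame, start_nt = starts0[first_atg],
        stop_nt = starts0[end_codon] + 3L, protein_seq = prot,
        has_stop = has_stop, length_aa = len_aa)
    }
    if (!require_atg) {
      # 5'-partial: first segment of the frame when it has no ATG before a stop
      seg0 <- which(seg == 0L)
      if (length(seg0) && !any(is_start[seg0])) {
        stop_i <- seg0[is_stop[seg0]]
        has_stop <- length(stop_i) == 1L
        end_codon <- if (has_stop) stop_i[1L] else max(seg0)
        len_aa <- end_codon - 1L + if (has_stop) 0L else 1L
        if (len_aa >= min_aa) {
          aa_end <- if (has_stop) end_codon - 1L else end_codon
          prot <- paste(ifelse(grepl("N", codons[1:aa_end], fixed = TRUE),
                               "X", .codon_table[codons[1:aa_end]]),
                        collapse = "")
          out[[length(out) + 1L]] <- data.table::data.table(
            orf_id = "", frame = frame, start_nt = starts0[1L],
            stop_nt = starts0[end_codon] + 3L, protein_seq = prot,
            has_stop = has_stop, length_aa = len_aa)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, -length_aa, start_nt)
  res[]
}

#' Translate a transcript database into candidate proteins
#'
#' Runs [find_orfs()] over a set of transcript sequences and emits the
#' candidate protein database plus an ORF table. lncRNAs use the strict
#' `> 100 aa` filter (kept iff `length_aa >= 101`); annotated mRNAs and
#' isoforms use `min_aa` as given (default 100). Multiple qualifying ORFs per
#' transcript are retained; protein ids are `<transcript_id>.orf<k>` in the
#' sort order of [find_orfs()].
#'
#' @param seqs named character vector of transcript sequences
#' @param biotype `"annotated_mrna"`, `"lncrna"` or `"isoform"`
#' @param min_aa minimum ORF length in residues for non-lncRNA biotypes
#' @param require_atg passed to [find_orfs()]
#' @return list with `proteins` (named character vector) and `orf_table`
#'   (`data.table`: orf_id, transcript_id, frame, start_nt, stop_nt,
#'   protein_seq, has_stop, length_aa)
#' @export
translate_database <- function(seqs, biotype = c("annotated_mrna", "lncrna",
                                                 "isoform"),
                               min_aa = 100L, require_atg = TRUE) {
  biotype <- match.arg(biotype)
  if (anyDuplicated(names(seqs)))
    stop("duplicate transcript IDs: ",
         names(seqs)[duplicated(names(seqs))][1L])
  eff_min <- if (biotype == "lncrna") 101L else as.integer(min_aa)
  tabs <- lapply(names(seqs), function(id) {
    orfs <- find_orfs(seqs[[id]], min_aa = eff_min, require_atg = require_atg)
    if (nrow(orfs)) {
      orfs$transcript_id <- id
      orfs$orf_id <- paste0(id, ".orf", seq_len(nrow(orfs)))
    }
    orfs
  })
  orf_table <- data.table::rbindlist(tabs, fill = TRUE)
  if (nrow(orf_table) == 0L)
    return(list(proteins = setNames(character(), character()),
                orf_table = orf_table))
  data.table::setcolorder(orf_table, c("orf_id", "transcript_id"))
  proteins <- setNames(orf_table$protein_seq, orf_table$orf_id)
  list(proteins = proteins, orf_table = orf_table)
}
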