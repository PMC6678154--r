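#' Construct a transcript model
#'
#' A `transcript_model` is the shared currency of the pipeline: a stranded,
#' multi-exon transcript with its mature (spliced) sequence. Genomic exon
#' coordinates are 1-based closed; exons are stored 5' to 3' in transcript
#' orientation, i.e. genomic-descending on the minus strand.
#'
#' @param transcript_id,gene_id,chrom identifiers
#' @param strand `"+"` or `"-"`
#' @param exons two-column integer matrix (`start`, `end`), 1-based closed,
#'   ordered 5'->3' in transcript orientation
#' @param spliced_seq mature mRNA sequence (may be `NA` until filled from a
#'   genome with [spliced_sequence()])
#' @param biotype one of `"annotated_mrna"`, `"lncrna"`, `"isoform"`
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             spliced_seq = NA_character_,
                             biotype = c("annotated_mrna", "lncrna", "isoform")) {
  biotype <- match.arg(biotype)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, "end"] < exons[, "start"]))
    stop("zero- or negative-length exon in ", transcript_id)
  # non-overlap + transcript orientation order
  gord <- order(exons[, "start"])
  if (any(exons[gord, "start"][-1L] <= exons[gord, "end"][-nrow(exons)]))
    stop("overlapping exons in ", transcript_id)
  expected <- if (strand == "+") gord else rev(gord)
  if (!identical(expected, seq_len(nrow(exons))))
    stop("exons of ", transcript_id, " are not ordered 5'->3' in transcript ",
         "orientation")
  widths <- exons[, "end"] - exons[, "start"] + 1L
  if (!is.na(spliced_seq)) {
    assert_nucleotides(spliced_seq, paste0("spliced_seq of ", transcript_id))
    if (nchar(spliced_seq) != sum(widths))
      stop("spliced_seq length ", nchar(spliced_seq), " != sum of exon widths ",
           sum(widths), " for ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 spliced_seq = spliced_seq, biotype = biotype),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (gene %s) %s%s, %d exon(s), %d nt, %s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              sum(x$exons[, "end"] - x$exons[, "start"] + 1L), x$biotype))
  invisible(x)
}

#' Extract the spliced (mature mRNA) sequence of a transcript
#'
#' Concatenates exon sequences 5'->3'; minus-strand transcripts are
#' reverse-complemented. Output is uppercase ACGTN.
#'
#' @param model a `transcript_model`
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences
#' @return nucleotide string
#' @export
spliced_sequence <- function(model, genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  chrom <- genome[[model$chrom]]
  if (is.null(chrom) || is.na(chrom))
    stop("chromosome ", model$chrom, " not in genome")
  if (any(model$exons[, "start"] < 1L | model$exons[, "end"] > nchar(chrom)))
    stop("exon out of chromosome bounds for ", model$transcript_id)
  # extract in genomic order, then orient
  gord <- order(model$exons[, "start"])
  pieces <- substring(chrom, model$exons[gord, "start"], model$exons[gord, "end"])
  s <- toupper(paste(pieces, collapse = ""))
  assert_nucleotides(s, paste0("genome sequence under ", model$transcript_id))
  if (model$strand == "-") revcomp(s) else s
}

## ---- FASTA ------------------------------------------------------------

#' Read a FASTA file of nucleotide sequences
#'
#' @param path FASTA file (plain or gzip)
#' @return named character vector, uppercase; alphabet restricted to ACGTN
#' @export
read_fasta_nt <- function(path) {
  x <- Biostrings::readBStringSet(path)
  s <- toupper(setNames(as.character(x), names(x)))
  assert_nucleotides(s, path)
  s
}

#' Read a FASTA file of protein sequences
#' @param path FASTA file
#' @return named character vector, uppercase
#' @export
read_fasta_aa <- function(path) {
  x <- Biostrings::readBStringSet(path)
  toupper(setNames(as.character(x), names(x)))
}

#' Write sequences as FASTA (60-column wrap)
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("write_fasta: all sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

## ---- GFF3 -------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Expects the conventional gene/mRNA/exon hierarchy (`transcript` is accepted
#' as a synonym of `mRNA`). One `transcript_model` is returned per mRNA, exons
#' ordered in transcript orientation. An optional `biotype` attribute on the
#' mRNA is honoured; default `annotated_mrna`.
#'
#' @param path GFF3 file
#' @return named list of `transcript_model` (names = transcript ids)
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  fields <- strsplit(raw[body], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", body[i], " in ", path, ": expected 9 columns")
    if (tolower(f[3L]) == "exon" && as.integer(f[5L]) < as.integer(f[4L]))
      stop("zero-length exon at line ", body[i], " in ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- tolower(as.character(gr$type))
  is_tx <- type %in% c("mrna", "transcript")
  is_exon <- type == "exon"
  tx_ids <- gr$ID[is_tx]
  tx_parent <- vapply(gr$Parent[is_tx], function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1L))
  tx_bt <- if ("biotype" %in% names(S4Vectors::mcols(gr)))
    gr$biotype[is_tx] else rep(NA_character_, sum(is_tx))
  if (is.null(gr$Parent))
    stop("no Parent attributes at all in ", path,
         " (exon with no parent mRNA)")
  exon_parent <- gr$Parent[is_exon]
  n_par <- lengths(exon_parent)
  if (any(n_par == 0L)) {
    idx <- which(is_exon)[which(n_par == 0L)[1L]]
    stop("exon with no Parent (feature ", idx, ", ",
         as.character(GenomicRanges::seqnames(gr))[idx], ":",
         GenomicRanges::start(gr)[idx], "-", GenomicRanges::end(gr)[idx],
         ") in ", path)
  }
  exon_df <- data.frame(
    parent = unlist(exon_parent),
    chrom = rep(as.character(GenomicRanges::seqnames(gr))[is_exon], n_par),
    start = rep(GenomicRanges::start(gr)[is_exon], n_par),
    end = rep(GenomicRanges::end(gr)[is_exon], n_par),
    strand = rep(as.character(GenomicRanges::strand(gr))[is_exon], n_par),
    stringsAsFactors = FALSE)
  orphan <- setdiff(unique(exon_df$parent), tx_ids)
  if (length(orphan))
    stop("exon Parent '", orphan[1L], "' has no mRNA feature in ", path)
  models <- vector("list", length(tx_ids))
  names(models) <- tx_ids
  for (i in seq_along(tx_ids)) {
    ed <- exon_df[exon_df$parent == tx_ids[i], , drop = FALSE]
    if (nrow(ed) == 0L) stop("mRNA ", tx_ids[i], " has no exons in ", path)
    strand <- ed$strand[1L]
    ord <- order(ed$start, decreasing = (strand == "-"))
    bt <- tx_bt[i]
    if (is.na(bt)) bt <- "annotated_mrna"
    models[[i]] <- transcript_model(
      transcript_id = tx_ids[i], gene_id = tx_parent[i], chrom = ed$chrom[1L],
      strand = strand, exons = cbind(start = ed$start[ord], end = ed$end[ord]),
      biotype = bt)
  }
  models
}

#' Write gene models as GFF3
#'
#' Deterministic output (no timestamps): gene, mRNA and exon features with
#' `ID`/`Parent` attributes and a `biotype` attribute on each mRNA.
#'
#' @param models list of `transcript_model`
#' @param path output file
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  gene_ids <- unique(vapply(models, `[[`, "", "gene_id"))
  by_gene <- split(models, vapply(models, `[[`, "", "gene_id"))
  for (g in gene_ids) {
    txs <- by_gene[[g]]
    gstart <- min(vapply(txs, function(m) min(m$exons[, "start"]), 0L))
    gend <- max(vapply(txs, function(m) max(m$exons[, "end"]), 0L))
    m1 <- txs[[1L]]
    lines <- c(lines, paste(m1$chrom, "pgxpipe", "gene", gstart, gend, ".",
                            m1$strand, ".", paste0("ID=", g), sep = "\t"))
    for (m in txs) {
      lines <- c(lines, paste(
        m$chrom, "pgxpipe", "mRNA", min(m$exons[, "start"]),
        max(m$exons[, "end"]), ".", m$strand, ".",
        paste0("ID=", m$transcript_id, ";Parent=", g, ";biotype=", m$biotype),
        sep = "\t"))
      ex <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
      for (k in seq_len(nrow(ex)))
        lines <- c(lines, paste(m$chrom, "pgxpipe", "exon", ex[k, "start"],
                                ex[k, "end"], ".", m$strand, ".",
                                paste0("Parent=", m$transcript_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- TSV tables -------------------------------------------------------

PSM_COLUMNS <- c("peptide", "protein_candidates", "score", "is_decoy",
                 "sample", "spectral_count")
DOMAIN_COLUMNS <- c("protein_id", "gene_id", "domains")

check_columns <- function(dt, required, path) {
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("missing mandatory column(s) ", paste(missing, collapse = ", "),
         " in ", path, "; columns found: ", paste(names(dt), collapse = ", "))
  invisible(TRUE)
}

#' Read a peptide-spectrum-match table
#'
#' Mandatory columns: `peptide`, `protein_candidates` (semicolon-separated,
#' may be empty), `score`, `is_decoy` (0/1/true/false), `sample`,
#' `spectral_count`. Unknown columns are preserved.
#'
#' @param path TSV with header
#' @return `data.table`, `is_decoy` as logical
#' @export
read_psm_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "peptide"))
  check_columns(dt, PSM_COLUMNS, path)
  dec <- tolower(as.character(dt$is_decoy))
  ok <- dec %in% c("0", "1", "true", "false")
  if (!all(ok))
    stop("invalid is_decoy value '", dt$is_decoy[!ok][1L], "' in ", path,
         " (allowed: 0,1,true,false)")
  dt$is_decoy <- dec %in% c("1", "true")
  if (any(dt$spectral_count < 1L))
    stop("spectral_count < 1 in ", path)
  bad <- grepl("[^A-Z]", dt$peptide)
  if (any(bad)) stop("non amino-acid peptide '", dt$peptide[bad][1L],
                     "' in ", path)
  dt
}

#' Read a domain-assignment table
#'
#' Columns `protein_id`, `gene_id`, `domains` (semicolon-separated set, may
#' be empty). `protein_id` must be unique.
#'
#' @param path TSV with header
#' @return `data.table` with a `domain_set` list-column of character vectors
#' @export
read_domain_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  check_columns(dt, DOMAIN_COLUMNS, path)
  if (anyDuplicated(dt$protein_id))
    stop("duplicate protein_id in ", path)
  dt$domain_set <- lapply(strsplit(dt$domains, ";", fixed = TRUE),
                          function(x) unique(x[nzchar(x)]))
  dt
}

#' Write a table as TSV
#'
#' Plain tab-separated output with header; logical columns are written as
#' 0/1 so tables round-trip bit-identically through [read_psm_table()].
#'
#' @param dt data.frame / data.table
#' @param path output file
#' @export
write_tsv <- function(dt, path) {
  dt <- data.table::as.data.table(dt)
  for (j in names(dt))
    if (is.logical(dt[[j]])) data.table::set(dt, j = j, value = as.integer(dt[[j]]))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
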