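# Peptide-to-database matching and two-peptide protein inference.

#' Map accepted peptides onto candidate protein databases
#'
#' Substring search with I/L collapsed on both sides (isobaric residues are
#' indistinguishable by MS). Uniqueness is computed hierarchically over the
#' union of databases:
#' \itemize{
#'   \item `isoform_unique` — maps to exactly one protein entry overall;
#'   \item `gene_unique` — maps to more than one entry, all of one gene;
#'   \item `shared` — maps to entries of several genes (a peptide hitting an
#'     annotated protein and a lncRNA ORF is `shared` and validates neither).
#' }
#' Peptides with no match anywhere are retained with empty `mapped_proteins`
#' and `uniqueness = "unmapped"`: they are the input to novel-reading-frame
#' discovery, not an error.
#'
#' @param accepted `data.table` of accepted target PSMs (columns `peptide`,
#'   `score`, `sample`, `spectral_count`)
#' @param databases named list of protein databases, e.g.
#'   `list(annotated = ..., lncrna_orf = ..., isoform_orf = ...)`; each a
#'   named character vector of sequences
#' @param protein_gene named character vector mapping protein id -> gene id
#'   (ids absent default to their own protein id)
#' @return `data.table` of peptide evidence: `peptide_key` (I->L collapsed),
#'   `raw_peptide`, per-sample SpC columns folded into `samples` list,
#'   `best_score`, `mapped_proteins` (list), `sources` (list, parallel to
#'   mapped_proteins), `genes` (list), `uniqueness`
#' @export
match_peptides <- function(accepted, databases, protein_gene = NULL) {
  accepted <- data.table::as.data.table(accepted)
  db_ids <- unlist(lapply(databases, names), use.names = FALSE)
  db_src <- rep(names(databases), vapply(databases, length, 0L))
  db_seq <- il_collapse(toupper(unlist(databases, use.names = FALSE)))
  if (anyDuplicated(db_ids))
    stop("duplicate protein id across databases: ",
         db_ids[duplicated(db_ids)][1L])
  gene_of <- function(pid) {
    if (!is.null(protein_gene) && pid %in% names(protein_gene))
      protein_gene[[pid]] else pid
  }
  key <- il_collapse(toupper(accepted$peptide))
  # aggregate PSM rows per peptide key
  ev <- data.table::data.table(
    peptide_key = key, raw_peptide = accepted$peptide,
    score = accepted$score, sample = accepted$sample,
    spectral_count = accepted$spectral_count)
  agg <- ev[, list(
    raw_peptide = raw_peptide[which.max(score)],
    best_score = max(score),
    samples = list(tapply(spectral_count, sample, sum))),
    by = "peptide_key"]
  uniq_keys <- agg$peptide_key
  hit_list <- lapply(uniq_keys, function(k) which(grepl(k, db_seq, fixed = TRUE)))
  agg$mapped_proteins <- lapply(hit_list, function(i) db_ids[i])
  agg$sources <- lapply(hit_list, function(i) db_src[i])
  agg$genes <- lapply(agg$mapped_proteins, function(p)
    unique(vapply(p, gene_of, character(1L), USE.NAMES = FALSE)))
  agg$uniqueness <- vapply(seq_len(nrow(agg)), function(i) {
    np <- length(agg$mapped_proteins[[i]])
    if (np == 0L) "unmapped"
    else if (np == 1L && agg$sources[[i]] %in% c("lncrna_orf", "isoform_orf"))
      "isoform_unique"
    else if (length(agg$genes[[i]]) == 1L) "gene_unique"
    else "shared"
  }, character(1L))
  agg
}

#' Infer validated proteins from peptide evidence
#'
#' A protein is validated when supported by at least `min_peptides` distinct
#' peptide keys. Proteins from the `lncrna_orf` and `isoform_orf` databases
#' must additionally carry at least one `isoform_unique` peptide (a peptide
#' mapping to that entry alone); without it, peptide evidence cannot
#' discriminate the ORF from the annotated protein it overlaps.
#'
#' Spectral counts are aggregated per sample over supporting peptides; for
#' `lncrna_orf`/`isoform_orf` entries only unique peptides contribute SpC
#' (shared peptides would double-count spectra already credited at gene
#' level).
#'
#' @param evidence output of [match_peptides()]
#' @param min_peptides distinct-peptide rule (default 2)
#' @param protein_lengths named integer vector, residues per protein id
#' @param protein_gene named character vector protein id -> gene id
#' @return `data.table` of protein groups: `protein_id`, `gene_id`, `source`,
#'   `n_distinct_peptides`, `n_unique_peptides`, `best_score`, `validated`,
#'   `peptides` (list), and per-sample SpC / distinct-peptide-count list
#'   columns `spc_per_sample`, `npep_per_sample`
#' @export
infer_proteins <- function(evidence, min_peptides = 2L, protein_lengths = NULL,
                           protein_gene = NULL) {
  ev <- data.table::as.data.table(evidence)
  ev <- ev[ev$uniqueness != "unmapped"]
  if (nrow(ev) == 0L)
    return(data.table::data.table(
      protein_id = character(), gene_id = character(), source = character(),
      n_distinct_peptides = integer(), n_unique_peptides = integer(),
      best_score = numeric(), validated = logical(), length_aa = integer(),
      peptides = list(), spc_per_sample = list(), npep_per_sample = list()))
  flat <- ev[, {
    idx <- seq_along(mapped_proteins[[1L]])
    list(protein_id = mapped_proteins[[1L]],
         source = sources[[1L]],
         unique_pep = rep(uniqueness == "isoform_unique", length(idx)))
  }, by = c("peptide_key", "best_score")]
  spc_of <- setNames(ev$samples, ev$peptide_key)
  groups <- flat[, {
    src <- source[1L]
    iso_like <- src %in% c("lncrna_orf", "isoform_orf")
    counted <- if (iso_like) peptide_key[unique_pep] else peptide_key
    spc <- list()
    npep <- list()
    for (k in counted) {
      s <- spc_of[[k]]
      for (nm in names(s)) {
        spc[[nm]] <- (if (is.null(spc[[nm]])) 0 else spc[[nm]]) + s[[nm]]
        npep[[nm]] <- (if (is.null(npep[[nm]])) 0L else npep[[nm]]) + 1L
      }
    }
    list(source = src,
         n_distinct_peptides = length(unique(peptide_key)),
         n_unique_peptides = sum(unique_pep),
         best_score = max(best_score),
         peptides = list(sort(unique(peptide_key))),
         spc_per_sample = list(spc),
         npep_per_sample = list(npep))
  }, by = "protein_id"]
  groups$gene_id <- vapply(groups$protein_id, function(pid) {
    if (!is.null(protein_gene) && pid %in% names(protein_gene))
      protein_gene[[pid]] else pid
  }, character(1L), USE.NAMES = FALSE)
  groups$length_aa <- if (is.null(protein_lengths)) NA_integer_ else
    as.integer(protein_lengths[groups$protein_id])
  iso_like <- groups$source %in% c("lncrna_orf", "isoform_orf")
  groups$validated <- groups$n_distinct_peptides >= min_peptides &
    (!iso_like | groups$n_unique_peptides >= 1L)
  data.table::setcolorder(groups, c("protein_id", "gene_id", "source"))
  groups[]
}
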