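# End-to-end orchestration: sequences in, validated/quantified/classified
# tables and a summary out. Every stage writes plain TSV/JSON; a manifest
# with content hashes makes determinism checkable.

#' Pipeline configuration
#'
#' Thresholds default to the analysis' stated values: peptide/protein FDR
#' 0.01, two-peptide rule, fold change >= 4 / <= 0.25, NMD distance 50 nt,
#' ORF length > 100 aa, trypsin with up to 2 missed cleavages, peptide
#' length 7..50.
#'
#' @param gff3,genome,lncrna,annotated_proteins,psms,domains input paths
#'   (`psms` is a character vector of PSM TSVs, one per sample)
#' @param out_dir output directory
#' @param fdr,min_peptides,up_fc,down_fc,nmd_nt,min_orf_aa,missed_cleavages,
#'   peptide_len,require_atg,correlation_method analysis thresholds
#' @param sample_a,sample_b sample ids (fold change is B over A)
#' @param seed integer seed (used only when simulation is requested)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(gff3 = NULL, genome = NULL, lncrna = NULL,
                            annotated_proteins = NULL, psms = NULL,
                            domains = NULL, out_dir = "pgx_out",
                            fdr = 0.01, min_peptides = 2L, up_fc = 4,
                            down_fc = 0.25, nmd_nt = 50L, min_orf_aa = 100L,
                            missed_cleavages = 2L, peptide_len = c(7L, 50L),
                            require_atg = TRUE,
                            correlation_method = "pearson",
                            sample_a = "seedling", sample_b = "leaf",
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

require_file <- function(path, what) {
  if (is.null(path) || !all(file.exists(path)))
    stop("[", what, "] missing input file: ",
         paste(path[!file.exists(path)], collapse = ", "))
  path
}

# protein id -> gene id map: ORF ids are <transcript>.orf<k>, annotated ids
# <transcript>.p<k>; transcripts map to genes via the models, lncRNA ORFs
# are their own gene
build_protein_gene <- function(protein_ids, models) {
  tx <- sub("\\.(orf|p)[0-9]+$", "", protein_ids)
  gene <- vapply(tx, function(t)
    if (!is.null(models[[t]])) models[[t]]$gene_id else t,
    character(1L), USE.NAMES = FALSE)
  setNames(gene, protein_ids)
}

#' Run the full re-annotation analysis
#'
#' Stages: read inputs -> build the three candidate protein databases ->
#' peptide-level target-decoy FDR -> peptide matching with uniqueness ->
#' protein-level FDR and two-peptide inference -> NSAF quantification and DE
#' -> NMD classification -> domain categories -> summary. All artifacts land
#' in `cfg$out_dir`; `manifest.tsv` lists each with its md5.
#'
#' @param cfg a [pipeline_config()]
#' @return (invisibly) list with the main in-memory results
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  message("[io] reading inputs")
  require_file(cfg$gff3, "io"); require_file(cfg$genome, "io")
  require_file(cfg$lncrna, "io"); require_file(cfg$annotated_proteins, "io")
  require_file(cfg$psms, "io")
  models <- read_gff3(cfg$gff3)
  genome <- read_fasta_nt(cfg$genome)
  for (id in names(models))
    models[[id]]$spliced_seq <- spliced_sequence(models[[id]], genome)
  lnc <- read_fasta_nt(cfg$lncrna)
  annotated <- read_fasta_aa(cfg$annotated_proteins)
  psms <- data.table::rbindlist(lapply(cfg$psms, read_psm_table),
                                fill = TRUE)

  message("[orf] translating candidate databases")
  iso_ids <- names(models)[vapply(models, `[[`, "", "biotype") == "isoform"]
  iso_seqs <- setNames(vapply(models[iso_ids], `[[`, "", "spliced_seq"),
                       iso_ids)
  lnc_db <- translate_database(lnc, "lncrna", require_atg = cfg$require_atg)
  iso_db <- translate_database(iso_seqs, "isoform", min_aa = cfg$min_orf_aa,
                               require_atg = cfg$require_atg)
  dbs <- list(annotated = annotated, lncrna_orf = lnc_db$proteins,
              isoform_orf = iso_db$proteins)
  protein_gene <- build_protein_gene(unlist(lapply(dbs, names),
                                           use.names = FALSE), models)

  message("[fdr] peptide-level target-decoy filtering")
  pep_fdr <- fdr_filter(psms, cfg$fdr)

  message("[match] mapping ", length(unique(pep_fdr$accepted$peptide)),
          " peptides against ", sum(lengths(dbs)), " proteins")
  evidence <- match_peptides(pep_fdr$accepted, dbs, protein_gene)
  lengths_aa <- setNames(nchar(unlist(dbs, use.names = FALSE)),
                         unlist(lapply(dbs, names), use.names = FALSE))
  groups <- infer_proteins(evidence, cfg$min_peptides, lengths_aa,
                           protein_gene)

  message("[fdr] protein-level target-decoy filtering")
  surviving_decoys <- psms[psms$is_decoy & psms$score >= pep_fdr$cutoff]
  decoy_groups <- if (nrow(surviving_decoys) > 0L) {
    ddb <- reverse_decoy(c(dbs$annotated, dbs$lncrna_orf, dbs$isoform_orf))
    ddb <- ddb[startsWith(names(ddb), "DECOY_")]
    dkeys <- il_collapse(ddb)
    hits <- lapply(il_collapse(surviving_decoys$peptide), function(k)
      names(ddb)[grepl(k, dkeys, fixed = TRUE)])
    dd <- data.table::data.table(
      protein_id = unlist(hits),
      best_score = rep(surviving_decoys$score, lengths(hits)))
    dd[, list(best_score = max(best_score)), by = "protein_id"]
  } else data.table::data.table(protein_id = character(),
                                best_score = numeric())
  prot_scores <- data.table::rbindlist(list(
    data.table::data.table(protein_id = groups$protein_id,
                           best_score = groups$best_score,
                           is_decoy = FALSE),
    if (nrow(decoy_groups)) data.table::data.table(
      protein_id = decoy_groups$protein_id,
      best_score = decoy_groups$best_score, is_decoy = TRUE)), fill = TRUE)
  pfdr <- protein_fdr_filter(prot_scores, cfg$fdr)
  groups$validated <- groups$validated &
    groups$protein_id %in% pfdr$accepted_ids
  validated <- groups[groups$validated == TRUE]

  message("[quant] NSAF quantification (", nrow(validated), " proteins)")
  quant <- quantify_proteins(validated, cfg$sample_a, cfg$sample_b,
                             cfg$min_peptides, cfg$up_fc, cfg$down_fc)
  de <- differential(quant, cfg$up_fc, cfg$down_fc)
  corr <- tryCatch(
    sample_correlation(quant$nsaf_a, quant$nsaf_b, cfg$correlation_method),
    error = function(e) NA_real_)

  message("[nmd] classifying ", length(iso_ids), " isoforms")
  nmd_calls <- if (nrow(iso_db$orf_table) > 0L)
    classify_nmd_set(models, iso_db$orf_table, cfg$nmd_nt)
  else data.table::data.table(transcript_id = character(),
                              is_nmd = logical())
  validated_iso <- validated$protein_id[validated$source == "isoform_orf"]
  validated_iso_tx <- unique(sub("\\.orf[0-9]+$", "", validated_iso))
  nmd_all <- tryCatch(nmd_composition(nmd_calls), error = function(e) NULL)
  nmd_val <- tryCatch(nmd_composition(nmd_calls, validated_iso_tx),
                      error = function(e) NULL)

  message("[domains] categorizing isoform domain sets")
  dom <- if (!is.null(cfg$domains) && file.exists(cfg$domains))
    classify_domain_table(read_domain_table(cfg$domains)) else NULL

  message("[report] assembling summary")
  tissue_ids <- function(nm_pep) quant$protein_id[quant[[nm_pep]] >=
                                                    cfg$min_peptides]
  ov <- overlap_summary(tissue_ids("npep_a"), tissue_ids("npep_b"))
  validated_lnc <- validated$protein_id[validated$source == "lncrna_orf"]
  summary <- list(
    thresholds = cfg[c("fdr", "min_peptides", "up_fc", "down_fc", "nmd_nt",
                       "min_orf_aa", "missed_cleavages", "peptide_len",
                       "require_atg", "sample_a", "sample_b")],
    peptide_fdr_cutoff = pep_fdr$cutoff,
    protein_fdr_cutoff = pfdr$cutoff,
    n_peptides_accepted = nrow(evidence),
    n_proteins_validated = nrow(validated),
    tissue_overlap = ov,
    nsaf_correlation = corr,
    de = de[c("n_up", "n_down", "n_total_de", "n_quantified")],
    lncrna = list(
      n_total = length(lnc), n_orf = length(dbs$lncrna_orf),
      n_validated = length(validated_lnc),
      percent_of_lncrnas = percent_of(length(validated_lnc),
                                      max(length(lnc), 1L), 2L)),
    isoforms = list(
      n_total = length(iso_ids),
      n_validated = length(validated_iso),
      n_genes = length(unique(protein_gene[validated_iso])),
      percent_of_isoforms = percent_of(length(validated_iso),
                                       max(length(iso_ids), 1L), 2L)),
    nmd = list(all_isoforms = nmd_all, validated_isoforms = nmd_val),
    domain_counts = if (!is.null(dom)) as.list(dom$counts) else NULL)

  flat_groups <- data.table::data.table(
    protein_id = groups$protein_id, gene_id = groups$gene_id,
    source = groups$source, length_aa = groups$length_aa,
    n_distinct_peptides = groups$n_distinct_peptides,
    n_unique_peptides = groups$n_unique_peptides,
    best_score = groups$best_score, validated = groups$validated,
    peptides = vapply(groups$peptides, paste, "", collapse = ";"))
  ev_out <- data.table::data.table(
    peptide_key = evidence$peptide_key, raw_peptide = evidence$raw_peptide,
    best_score = evidence$best_score, uniqueness = evidence$uniqueness,
    mapped_proteins = vapply(evidence$mapped_proteins, paste, "",
                             collapse = ";"))
  artifacts <- c(
    proteins_lncrna_orf.fasta = NA, proteins_isoform_orf.fasta = NA,
    evidence.tsv = NA, protein_groups.tsv = NA, quant.tsv = NA,
    nmd_calls.tsv = NA, domain_categories.tsv = NA, summary.json = NA)
  p <- function(f) file.path(cfg$out_dir, f)
  if (length(dbs$lncrna_orf)) write_fasta(dbs$lncrna_orf,
                                          p("proteins_lncrna_orf.fasta"))
  if (length(dbs$isoform_orf)) write_fasta(dbs$isoform_orf,
                                           p("proteins_isoform_orf.fasta"))
  write_tsv(ev_out, p("evidence.tsv"))
  write_tsv(flat_groups, p("protein_groups.tsv"))
  write_tsv(de$table, p("quant.tsv"))
  if (nrow(nmd_calls)) write_tsv(nmd_calls, p("nmd_calls.tsv"))
  if (!is.null(dom) && nrow(dom$categories))
    write_tsv(dom$categories, p("domain_categories.tsv"))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  write_manifest(cfg$out_dir)
  invisible(list(models = models, databases = dbs, evidence = evidence,
                 groups = groups, quant = de$table, de = de,
                 nmd_calls = nmd_calls, domains = dom, summary = summary))
}

#' Write a content-hash manifest of a run directory
#'
#' @param dir run directory
#' @return path to `manifest.tsv` (file, md5), sorted by file name
#' @export
write_manifest <- function(dir) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.tsv"))
  md5 <- unname(tools::md5sum(file.path(dir, files)))
  write_tsv(data.table::data.table(file = files, md5 = md5),
            file.path(dir, "manifest.tsv"))
}
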