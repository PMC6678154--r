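# Synthetic-study generator: a toy multi-exon genome with annotated genes,
# AS/APA transcript isoforms, lncRNAs, a known true proteome, and PSM tables
# for two tissues. Every emitted sequence has exactly one truth row, so every
# downstream metric (lncRNA re-annotation sensitivity, NMD classification
# accuracy, FDR calibration, DE recovery) is computable from truth alone.

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis assumes: roughly half of
#' predicted lncRNAs harbor a translatable ORF (0.5), about 22% of transcript
#' isoforms carry a premature termination codon in NMD-triggering position
#' (0.22), roughly a third of annotated genes are detected by MS (0.32), and
#' a small fraction of isoforms (3.5%) gains isoform-unique peptide support.
#'
#' @param seed integer; one global seed governs all randomness
#' @param n_genes number of annotated genes (>= 1)
#' @param n_lncrnas number of predicted lncRNAs
#' @param mean_isoforms_per_gene mean alternative isoforms per gene
#'   (1 + Poisson(mean - 1))
#' @param frac_genes_detected proportion of genes detected by MS
#' @param frac_lncrna_coding proportion of lncRNAs built with an ATG ORF
#'   > 100 aa
#' @param frac_isoform_nmd proportion of isoforms constructed with a PTC
#'   >= 50 nt upstream of the last junction
#' @param frac_isoform_detected proportion of isoforms given isoform-unique
#'   peptide support
#' @param frac_single_peptide proportion of detected proteins forced to
#'   exactly one peptide (exercises the two-peptide rule)
#' @param frac_forced_de proportion of detected proteins with a planted
#'   |log2 FC| >= 2 tissue effect
#' @param decoy_score_shift score-unit gap between true-target and
#'   decoy/noise score distributions (sd 1 each)
#' @param spc_dispersion negative-binomial dispersion of spectral counts
#'   (size = 1/dispersion)
#' @param tissue_effect_sd SD of the null log2 fold change between tissues
#' @param noise_psm_frac incorrect-target PSMs as a fraction of true PSMs
#'   (matched 1:1 by decoy PSMs, same score distribution)
#' @param mean_peptides_detected mean distinct peptides emitted per detected
#'   protein
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 300L, n_lncrnas = 60L,
                       mean_isoforms_per_gene = 2,
                       frac_genes_detected = 0.32,
                       frac_lncrna_coding = 0.5,
                       frac_isoform_nmd = 0.22,
                       frac_isoform_detected = 0.035,
                       frac_single_peptide = 0.05,
                       frac_forced_de = 0.1,
                       decoy_score_shift = 6,
                       spc_dispersion = 0.5,
                       tissue_effect_sd = 0.8,
                       noise_psm_frac = 0.05,
                       mean_peptides_detected = 5) {
  cfg <- as.list(environment())
  props <- c("frac_genes_detected", "frac_lncrna_coding", "frac_isoform_nmd",
             "frac_isoform_detected", "frac_single_peptide", "frac_forced_de",
             "noise_psm_frac")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0,1]")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

random_dna <- function(n, no_atg = FALSE) {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (no_atg) while (grepl("ATG", s, fixed = TRUE))
    s <- sub("ATG", "ACG", s, fixed = TRUE)
  s
}

random_cds <- function(n_aa) {
  # ATG + (n_aa - 1) non-stop codons + stop; translates to n_aa residues
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, n_aa - 1L, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# ---- gene geometry in mature-mRNA space --------------------------------

# junction positions: E-1 ascending cut points in (lo, hi), min gap
sample_junctions <- function(n, lo, hi, min_gap = 50L, tries = 50L) {
  if (n == 0L) return(integer())
  for (i in seq_len(tries)) {
    j <- sort(sample(seq.int(lo, hi), n))
    if (n == 1L || all(diff(j) >= min_gap)) return(j)
  }
  # fall back to evenly spaced
  as.integer(round(seq(lo, hi, length.out = n + 2L)))[2:(n + 1L)]
}

design_gene <- function(gene_id, cfg) {
  n_ex <- sample(4:6, 1L)
  p_aa <- sample(180:380, 1L)
  cds_len <- 3L * (p_aa + 1L)
  u5 <- sample(30:80, 1L)
  u3 <- sample(100:200, 1L)
  u5_seq <- random_dna(u5, no_atg = TRUE)
  cds_seq <- random_cds(p_aa)
  u3_seq <- random_dna(u3, no_atg = TRUE)
  mature <- paste0(u5_seq, cds_seq, u3_seq)
  total <- u5 + cds_len + u3
  stop_end <- u5 + cds_len                 # 0-based exclusive end of stop
  m_last <- total - (u3 + sample(30:90, 1L))  # last exon start; stop inside
  inner <- sample_junctions(n_ex - 2L, u5 + 30L, m_last - 60L)
  junc <- c(inner, m_last)                 # E-1 junction positions, mature
  # make one internal exon fully inside the CDS skippable in frame:
  # exon k spans [junc[k-1], junc[k]); adjust its 3' junction so len %% 3 == 0
  widths <- diff(c(0L, junc, total))
  skip_if <- NA_integer_; skip_fs <- NA_integer_
  for (k in seq_len(n_ex - 2L) + 1L) {     # internal exons 2..E-1
    lo <- junc[k - 1L]; hi <- junc[k]
    inside_cds <- lo >= u5 + 3L && hi <= stop_end - 66L
    long_enough_left <- (cds_len - (hi - lo)) >= 309L
    if (inside_cds && long_enough_left) {
      if (is.na(skip_if)) {
        shift <- (hi - lo) %% 3L
        junc[k] <- hi - shift              # now in frame
        skip_if <- k
      } else if (is.na(skip_fs) && (hi - lo) %% 3L != 0L &&
                 lo >= u5 + 330L) {
        skip_fs <- k
      }
    }
  }
  widths <- diff(c(0L, junc, total))
  list(gene_id = gene_id, n_ex = n_ex, p_aa = p_aa, u5 = u5, u3 = u3,
       cds_len = cds_len, stop_end = stop_end, mature = mature,
       junc = junc, widths = widths, skip_if = skip_if, skip_fs = skip_fs)
}

# mature pieces of a gene design, one per exon
exon_pieces <- function(g) {
  bounds <- c(0L, g$junc, nchar(g$mature))
  substring(g$mature, bounds[-length(bounds)] + 1L, bounds[-1L])
}

# ---- isoform constructions (mature space) ------------------------------

# returns list(kind, mature, keep_exons, split_in, novel_seq, d_intended)
design_isoform <- function(g, want_nmd, used, cfg) {
  pieces <- exon_pieces(g)
  E <- g$n_ex
  mk_alt_last <- function(d_target) {
    split_m <- g$stop_end + d_target       # new last junction position
    split_in <- split_m - g$junc[E - 1L]   # kept bases of old last exon
    novel <- random_dna(sample(80:150, 1L), no_atg = TRUE)
    mature <- paste0(paste(pieces[1:(E - 1L)], collapse = ""),
                     substr(pieces[E], 1L, split_in), novel)
    list(kind = "alt_last", mature = mature, keep_exons = seq_len(E - 1L),
         split_in = split_in, novel_seq = novel, d_intended = d_target)
  }
  mk_skip <- function(k, kind) {
    mature <- paste(pieces[-k], collapse = "")
    list(kind = kind, mature = mature, keep_exons = setdiff(seq_len(E), k),
         split_in = NA_integer_, novel_seq = NA_character_,
         d_intended = NA_integer_)
  }
  if (want_nmd) {
    # prefer a frameshifting exon skip (yields isoform-unique peptides);
    # verify the realized PTC position, else fall back to an alternative
    # last exon placing the normal stop >= 50 nt upstream of a new junction
    if (!is.na(g$skip_fs) && !("fs_skip" %in% used)) {
      cand <- mk_skip(g$skip_fs, "fs_skip")
      orfs <- find_orfs(cand$mature, min_aa = 101L)
      if (nrow(orfs) > 0L) {
        top <- orfs[1L]
        w <- nchar(pieces[cand$keep_exons])
        lj <- sum(w[-length(w)])
        if (top$has_stop && (lj - top$stop_nt) >= 50L) return(cand)
      }
    }
    d_hi <- min(g$u3 - 10L, 140L)
    return(mk_alt_last(sample(50:d_hi, 1L)))
  }
  # non-NMD: in-frame skip when available and clean, else short-3'UTR APA
  if (!is.na(g$skip_if) && !("inframe_skip" %in% used)) {
    cand <- mk_skip(g$skip_if, "inframe_skip")
    expected_aa <- g$p_aa - g$widths[g$skip_if] %/% 3L
    orfs <- find_orfs(cand$mature, min_aa = 101L)
    if (nrow(orfs) > 0L && orfs$has_stop[1L] &&
        orfs$length_aa[1L] >= expected_aa - 2L)   # no PTC introduced
      return(cand)
  }
  mk_alt_last(sample(5:45, 1L))
}

# ---- genomic embedding -------------------------------------------------

# lay a gene and its isoforms onto the genome string being built.
# returns list(segment, models, novel_used) with absolute coordinates
embed_gene <- function(g, isoforms, offset, chrom, strand) {
  pieces <- exon_pieces(g)
  E <- g$n_ex
  introns <- vapply(seq_len(E - 1L), function(i)
    random_dna(sample(60:150, 1L)), character(1L))
  tail_len <- 80L + sum(vapply(isoforms, function(iso)
    if (iso$kind == "alt_last") nchar(iso$novel_seq) + 40L else 0L, 0L))
  # forward construction string: exons + introns + tail (transcript sense)
  parts <- character(2L * E)
  parts[seq(1L, by = 2L, length.out = E)] <- pieces
  parts[seq(2L, by = 2L, length.out = E - 1L)] <- introns
  tail_seq <- random_dna(tail_len, no_atg = TRUE)
  # place novel exons inside the tail at known offsets
  novel_off <- integer(length(isoforms))
  cursor <- 40L
  for (i in seq_along(isoforms)) {
    if (isoforms[[i]]$kind == "alt_last") {
      nl <- nchar(isoforms[[i]]$novel_seq)
      substr(tail_seq, cursor + 1L, cursor + nl) <- isoforms[[i]]$novel_seq
      novel_off[i] <- cursor
      cursor <- cursor + nl + 40L
    }
  }
  fwd <- paste0(paste(parts, collapse = ""), tail_seq)
  seg_len <- nchar(fwd)
  # forward-string start offset (0-based) of each exon piece and of the tail
  piece_off <- cumsum(c(0L, nchar(parts)))[seq(1L, by = 2L, length.out = E)]
  tail_off <- seg_len - tail_len
  # map a forward-string interval [p0, p1) to absolute genomic (1-based closed)
  to_genomic <- function(p0, p1) {
    if (strand == "+") c(offset + p0 + 1L, offset + p1)
    else c(offset + seg_len - p1 + 1L, offset + seg_len - p0)
  }
  segment <- if (strand == "+") fwd else revcomp(fwd)
  exon_g <- t(vapply(seq_len(E), function(k)
    to_genomic(piece_off[k], piece_off[k] + nchar(pieces[k])), integer(2L)))
  primary <- transcript_model(
    transcript_id = paste0("tx_", g$gene_id, "_0"), gene_id = g$gene_id,
    chrom = chrom, strand = strand,
    exons = exon_g, spliced_seq = g$mature, biotype = "annotated_mrna")
  models <- list(primary)
  for (i in seq_along(isoforms)) {
    iso <- isoforms[[i]]
    tid <- paste0("tx_", g$gene_id, "_", i)
    if (iso$kind == "alt_last") {
      kept <- exon_g[seq_len(E - 1L), , drop = FALSE]
      lastE <- to_genomic(piece_off[E], piece_off[E] + iso$split_in)
      novel <- to_genomic(tail_off + novel_off[i],
                          tail_off + novel_off[i] + nchar(iso$novel_seq))
      ex <- rbind(kept, lastE, novel)
    } else {
      ex <- exon_g[iso$keep_exons, , drop = FALSE]
    }
    models[[i + 1L]] <- transcript_model(
      transcript_id = tid, gene_id = g$gene_id, chrom = chrom,
      strand = strand, exons = ex, spliced_seq = iso$mature,
      biotype = "isoform")
  }
  list(segment = segment, models = models)
}

# ---- lncRNAs -----------------------------------------------------------

design_lncrna <- function(id, coding, tries = 25L) {
  if (coding) {
    n_aa <- sample(101:250, 1L)
    pad5 <- random_dna(sample(20:80, 1L), no_atg = TRUE)
    pad3 <- random_dna(sample(20:120, 1L))
    list(id = id, seq = paste0(pad5, random_cds(n_aa), pad3),
         coding = TRUE, n_aa = n_aa)
  } else {
    for (i in seq_len(tries)) {
      s <- random_dna(sample(400:1200, 1L))
      if (nrow(find_orfs(s, min_aa = 101L)) == 0L)
        return(list(id = id, seq = s, coding = FALSE, n_aa = NA_integer_))
    }
    stop("could not build a noncoding lncRNA in ", tries, " tries")
  }
}

# ---- main generators ---------------------------------------------------

#' Simulate the toy study: genome, gene models, isoforms, lncRNAs, truth
#'
#' Writes `genome.fasta`, `models.gff3`, `lncrna.fasta`,
#' `proteins_annotated.fasta` and `truth.tsv` into `out_dir` and returns the
#' pieces invisibly. Identical configs give byte-identical files.
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory (created if needed); `NULL` to skip writing
#' @return (invisibly) list: genome, models, lncrnas, proteins_annotated,
#'   truth (`data.table`)
#' @export
simulate_genome_and_models <- function(cfg, out_dir = NULL) {
  set.seed(cfg$seed)
  chrom <- "chr1"
  genome_parts <- character()
  offset <- 0L
  all_models <- list()
  truth <- list()
  ann_proteins <- character()
  for (gi in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("g%04d", gi)
    g <- design_gene(gene_id, cfg)
    n_iso <- 1L + rpois(1L, max(cfg$mean_isoforms_per_gene - 1, 0))
    nmd_flags <- rbinom(n_iso, 1L, cfg$frac_isoform_nmd) == 1L
    isoforms <- list(); used <- character()
    for (k in seq_len(n_iso)) {
      iso <- design_isoform(g, nmd_flags[k], used, cfg)
      used <- c(used, iso$kind)
      isoforms[[k]] <- iso
    }
    strand <- sample(c("+", "-"), 1L)
    emb <- embed_gene(g, isoforms, offset, chrom, strand)
    spacer <- random_dna(50L)
    genome_parts <- c(genome_parts, emb$segment, spacer)
    offset <- offset + nchar(emb$segment) + 50L
    all_models <- c(all_models, emb$models)
    # truth rows: primary + isoforms; realized ORF/NMD status recomputed
    # from the constructed mature sequences (generator-side arithmetic)
    prim <- emb$models[[1L]]
    prot <- translate_nt(substr(g$mature, g$u5 + 1L, g$stop_end - 3L))
    ann_id <- paste0(prim$transcript_id, ".p1")
    ann_proteins[[ann_id]] <- prot
    truth[[length(truth) + 1L]] <- data.table::data.table(
      id = prim$transcript_id, type = "gene_primary", gene_id = gene_id,
      construction = "primary", coding = TRUE,
      protein_id = ann_id, protein_len = nchar(prot),
      nmd = FALSE, d = NA_integer_)
    for (k in seq_len(n_iso)) {
      m <- emb$models[[k + 1L]]
      orfs <- find_orfs(m$spliced_seq, min_aa = 100L)
      w <- m$exons[, "end"] - m$exons[, "start"] + 1L
      lj <- if (length(w) >= 2L) sum(w[-length(w)]) else NA_integer_
      coding <- nrow(orfs) > 0L
      d <- if (coding && !is.na(lj)) lj - orfs$stop_nt[1L] else NA_integer_
      is_nmd <- coding && !is.na(d) && isTRUE(orfs$has_stop[1L]) && d >= 50L
      truth[[length(truth) + 1L]] <- data.table::data.table(
        id = m$transcript_id, type = "isoform", gene_id = gene_id,
        construction = isoforms[[k]]$kind, coding = coding,
        protein_id = if (coding) paste0(m$transcript_id, ".orf1") else
          NA_character_,
        protein_len = if (coding) orfs$length_aa[1L] else NA_integer_,
        nmd = is_nmd, d = d)
    }
  }
  genome <- setNames(paste(genome_parts, collapse = ""), chrom)
  # lncRNAs
  lnc_coding <- rbinom(cfg$n_lncrnas, 1L, cfg$frac_lncrna_coding) == 1L
  lncrnas <- character()
  for (li in seq_len(cfg$n_lncrnas)) {
    id <- sprintf("lnc%04d", li)
    d <- design_lncrna(id, lnc_coding[li])
    lncrnas[[id]] <- d$seq
    truth[[length(truth) + 1L]] <- data.table::data.table(
      id = id, type = "lncrna", gene_id = id, construction = "lncrna",
      coding = d$coding,
      protein_id = if (d$coding) paste0(id, ".orf1") else NA_character_,
      protein_len = d$n_aa, nmd = FALSE, d = NA_integer_)
  }
  truth <- data.table::rbindlist(truth)
  names(all_models) <- vapply(all_models, `[[`, "", "transcript_id")
  # internal consistency: designed mature sequences must be re-extractable
  for (m in all_models)
    stopifnot(identical(spliced_sequence(m, genome), m$spliced_seq))
  out <- list(genome = genome, models = all_models, lncrnas = lncrnas,
              proteins_annotated = ann_proteins, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$genome, file.path(out_dir, "genome.fasta"))
    write_gff3(out$models, file.path(out_dir, "models.gff3"))
    write_fasta(out$lncrnas, file.path(out_dir, "lncrna.fasta"))
    write_fasta(out$proteins_annotated,
                file.path(out_dir, "proteins_annotated.fasta"))
    write_tsv(out$truth, file.path(out_dir, "truth.tsv"))
  }
  invisible(out)
}
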