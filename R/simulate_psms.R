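# PSM-table and domain-table simulation on top of the simulated sequences.
# Decoys come from the pipeline's own reverse_decoy(), so the FDR stage sees
# exactly the decoy space it models. Incorrect-target PSMs (random peptides,
# decoy-distributed scores) are planted 1:1 with decoy PSMs, which is what
# makes the D/T estimator calibrated and realized FDP measurable from truth.

SIM_SAMPLES <- c("seedling", "leaf")
TRUE_SCORE_MEAN <- 6    # target score distribution N(6, 1); decoys/noise
                        # are shifted down by cfg$decoy_score_shift

#' Simulate two-tissue PSM tables for a simulated study
#'
#' Chooses the detected fraction of annotated proteins, gives every coding
#' lncRNA ORF peptide support, grants a small fraction of isoforms
#' isoform-unique peptide support, and draws spectral counts per tissue from
#' a negative binomial with mean proportional to abundance x protein length.
#' A configurable subset of detected proteins gets exactly one peptide, and a
#' subset of tissue effects is forced beyond |log2 FC| >= 2.
#'
#' @param sim output of [simulate_genome_and_models()]
#' @param cfg the same [sim_config()]
#' @param out_dir directory for `psms_<sample>.tsv`, `detection_truth.tsv`;
#'   `NULL` to skip writing
#' @return (invisibly) list: `psms` (named list of two `data.table`s),
#'   `detection` (per-protein truth: detected, abundances, true_log2fc,
#'   forced_de, n_peptides, n_unique_peptides), `databases` (the three
#'   protein databases used)
#' @export
simulate_psms <- function(sim, cfg, out_dir = NULL) {
  set.seed(cfg$seed + 1000003L)
  iso_ids <- sim$truth$id[sim$truth$type == "isoform"]
  iso_seqs <- setNames(
    vapply(sim$models[iso_ids], `[[`, "", "spliced_seq"), iso_ids)
  dbs <- list(
    annotated = sim$proteins_annotated,
    lncrna_orf = translate_database(sim$lncrnas, "lncrna")$proteins,
    isoform_orf = translate_database(iso_seqs, "isoform")$proteins)
  all_prot <- c(dbs$annotated, dbs$lncrna_orf, dbs$isoform_orf)
  all_keys <- il_collapse(all_prot)
  # tryptic peptide pool per protein; uniqueness by substring search against
  # every database entry (I/L collapsed), exactly as the matcher sees it
  pools <- lapply(all_prot, function(p)
    digest(p, missed_cleavages = 0L, min_len = 7L, max_len = 50L))
  n_hits <- function(pep) sum(grepl(il_collapse(pep), all_keys, fixed = TRUE))
  # ---- choose detected proteins ---------------------------------------
  tr <- sim$truth
  genes_detected <- tr$id[tr$type == "gene_primary"][
    rbinom(sum(tr$type == "gene_primary"), 1L, cfg$frac_genes_detected) == 1L]
  det_ann <- tr$protein_id[tr$type == "gene_primary" & tr$id %in% genes_detected]
  det_lnc <- tr$protein_id[tr$type == "lncrna" & tr$coding]
  det_lnc <- det_lnc[det_lnc %in% names(dbs$lncrna_orf)]
  iso_cand <- tr$protein_id[tr$type == "isoform" & tr$coding &
                              tr$protein_id %in% names(dbs$isoform_orf)]
  # walk candidates in random order until enough isoforms with >= 1
  # unique (single-hit) peptide are found; alternative-last-exon isoforms
  # encode the annotated protein verbatim and can never qualify
  n_iso_target <- max(0L, round(cfg$frac_isoform_detected * length(iso_cand)))
  iso_unique_pool <- list()
  det_iso <- character()
  for (pid in sample(iso_cand)) {
    if (length(det_iso) >= n_iso_target) break
    uniq <- Filter(function(pep) n_hits(pep) == 1L, pools[[pid]])
    if (length(uniq) >= 1L) {
      iso_unique_pool[[pid]] <- uniq
      det_iso <- c(det_iso, pid)
    }
  }
  detected <- c(det_ann, det_lnc, det_iso)
  # ---- abundances and tissue effects ----------------------------------
  n_det <- length(detected)
  abundance_a <- rlnorm(n_det, meanlog = log(0.06), sdlog = 0.7)
  lfc <- rnorm(n_det, 0, cfg$tissue_effect_sd)
  forced <- rbinom(n_det, 1L, cfg$frac_forced_de) == 1L
  lfc[forced] <- sample(c(-1, 1), sum(forced), replace = TRUE) *
    (2 + stats::rexp(sum(forced), rate = 2))
  abundance_b <- abundance_a * 2^lfc
  single_pep <- rbinom(n_det, 1L, cfg$frac_single_peptide) == 1L
  # ---- peptide selection per detected protein -------------------------
  chosen <- vector("list", n_det)
  for (i in seq_len(n_det)) {
    pid <- detected[i]
    pool <- pools[[pid]]
    if (!length(pool)) next
    n_pep <- if (single_pep[i]) 1L else
      max(2L, min(length(pool), 2L + rpois(1L, cfg$mean_peptides_detected - 2L)))
    n_pep <- min(n_pep, length(pool))
    if (pid %in% det_iso) {
      uniq <- iso_unique_pool[[pid]]
      take_u <- uniq[seq_len(min(2L, length(uniq)))]
      rest <- setdiff(pool, take_u)
      chosen[[i]] <- c(take_u, if (n_pep > length(take_u))
        sample(rest, min(n_pep - length(take_u), length(rest))) else character())
    } else {
      chosen[[i]] <- sample(pool, n_pep)
    }
  }
  empty_pool <- vapply(chosen, is.null, TRUE) |
    vapply(chosen, length, 0L) == 0L
  detection <- data.table::data.table(
    protein_id = detected,
    source = c(rep("annotated", length(det_ann)),
               rep("lncrna_orf", length(det_lnc)),
               rep("isoform_orf", length(det_iso))),
    detected = !empty_pool, single_peptide = single_pep,
    abundance_seedling = abundance_a, abundance_leaf = abundance_b,
    true_log2fc = lfc, forced_de = forced,
    n_peptides = vapply(chosen, length, 0L),
    n_unique_peptides = vapply(seq_len(n_det), function(i)
      if (empty_pool[i]) 0L else
        sum(vapply(chosen[[i]], n_hits, 0L) == 1L), 0L))
  # ---- spectral counts and PSM rows -----------------------------------
  size <- 1 / cfg$spc_dispersion
  psms <- list()
  for (s_i in seq_along(SIM_SAMPLES)) {
    smp <- SIM_SAMPLES[s_i]
    ab <- if (smp == "seedling") abundance_a else abundance_b
    rows <- list()
    for (i in seq_len(n_det)) {
      if (empty_pool[i]) next
      pid <- detected[i]
      L <- nchar(all_prot[[pid]])
      peps <- chosen[[i]]
      total <- rnbinom(1L, mu = ab[i] * L, size = size)
      # low totals thin the observed peptide set: a protein scarce in one
      # tissue is seen on fewer (possibly zero) peptides there
      k_obs <- min(length(peps), total)
      if (k_obs == 0L) next
      obs <- if (k_obs == length(peps)) peps else sample(peps, k_obs)
      spc <- as.vector(rmultinom(1L, total - k_obs, rep(1, k_obs))) + 1L
      rows[[length(rows) + 1L]] <- data.table::data.table(
        peptide = obs, protein_candidates = pid,
        score = round(rnorm(k_obs, TRUE_SCORE_MEAN, 1), 4),
        is_decoy = 0L, sample = smp, spectral_count = spc,
        truth_correct = 1L)
    }
    true_tab <- data.table::rbindlist(rows)
    n_noise <- max(1L, round(cfg$noise_psm_frac * nrow(true_tab)))
    noise_pep <- vapply(seq_len(n_noise), function(j)
      paste(sample(names(AVG_RESIDUE_MASS), sample(8:20, 1L), replace = TRUE),
            collapse = ""), character(1L))
    noise_tab <- data.table::data.table(
      peptide = noise_pep, protein_candidates = "",
      score = round(rnorm(n_noise, TRUE_SCORE_MEAN - cfg$decoy_score_shift, 1), 4),
      is_decoy = 0L, sample = smp,
      spectral_count = sample(1:2, n_noise, replace = TRUE),
      truth_correct = 0L)
    decoy_db <- reverse_decoy(all_prot)
    decoy_pool <- unique(unlist(lapply(
      sample(names(all_prot), min(80L, length(all_prot))), function(pid)
        digest(decoy_db[[paste0("DECOY_", pid)]], 0L, 7L, 50L)),
      use.names = FALSE))
    decoy_pep <- sample(decoy_pool, min(n_noise, length(decoy_pool)))
    decoy_tab <- data.table::data.table(
      peptide = decoy_pep, protein_candidates = "",
      score = round(rnorm(length(decoy_pep),
                          TRUE_SCORE_MEAN - cfg$decoy_score_shift, 1), 4),
      is_decoy = 1L, sample = smp,
      spectral_count = sample(1:2, length(decoy_pep), replace = TRUE),
      truth_correct = 0L)
    psms[[smp]] <- data.table::rbindlist(list(true_tab, noise_tab, decoy_tab))
  }
  # record what was actually emitted (thinning may drop peptides): distinct
  # peptides per protein over both tissues, and how many are single-hit
  emitted <- data.table::rbindlist(psms)
  emitted <- emitted[emitted$truth_correct == 1L]
  by_prot <- split(emitted$peptide, emitted$protein_candidates)
  detection$n_peptides <- vapply(detection$protein_id, function(pid)
    length(unique(by_prot[[pid]])), 0L)
  detection$n_unique_peptides <- vapply(detection$protein_id, function(pid) {
    u <- unique(by_prot[[pid]])
    if (!length(u)) 0L else sum(vapply(u, n_hits, 0L) == 1L)
  }, 0L)
  detection$detected <- detection$n_peptides > 0L
  out <- list(psms = psms, detection = detection, databases = dbs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (smp in SIM_SAMPLES)
      write_tsv(psms[[smp]], file.path(out_dir, paste0("psms_", smp, ".tsv")))
    write_tsv(detection, file.path(out_dir, "detection_truth.tsv"))
  }
  invisible(out)
}

#' Simulate domain assignments with planted category structure
#'
#' For genes with at least two coding isoform proteins, plants one of the
#' four domain-composition categories (proportions follow the mix observed
#' in plant isoform studies: superset 0.35, partial 0.22, disjoint 0.16,
#' identical 0.27) on the first two isoform proteins and records the planted
#' label.
#'
#' @param sim output of [simulate_genome_and_models()]
#' @param cfg a [sim_config()]
#' @param out_dir directory for `domains.tsv` and `domain_truth.tsv`; `NULL`
#'   to skip writing
#' @return (invisibly) list: `domains` (`data.table` protein_id, gene_id,
#'   domains), `truth` (`data.table` gene_id, category)
#' @export
simulate_domains <- function(sim, cfg, out_dir = NULL) {
  set.seed(cfg$seed + 2000003L)
  cat_probs <- c("1_superset" = 0.35, "2_partial_overlap" = 0.22,
                 "3_disjoint" = 0.16, "4_identical" = 0.27)
  iso <- sim$truth[sim$truth$type == "isoform" & sim$truth$coding]
  rows <- list(); truth <- list()
  for (g in unique(iso$gene_id)) {
    pids <- iso$protein_id[iso$gene_id == g]
    if (length(pids) < 2L) next
    pids <- pids[1:2]
    cat <- sample(names(cat_probs), 1L, prob = cat_probs)
    base <- paste0("DOM_", g, "_", 1:4)
    sets <- switch(cat,
      "4_identical" = list(base[1:2], base[1:2]),
      "1_superset" = list(base[1:3], base[1:2]),
      "2_partial_overlap" = list(base[1:2], base[2:3]),
      "3_disjoint" = list(base[1], base[2]))
    for (j in 1:2)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        protein_id = pids[j], gene_id = g,
        domains = paste(sets[[j]], collapse = ";"))
    truth[[length(truth) + 1L]] <- data.table::data.table(
      gene_id = g, category = cat)
  }
  domains <- data.table::rbindlist(rows)
  truth <- data.table::rbindlist(truth)
  out <- list(domains = domains, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(domains, file.path(out_dir, "domains.tsv"))
    write_tsv(truth, file.path(out_dir, "domain_truth.tsv"))
  }
  invisible(out)
}

#' Simulate a complete study
#'
#' Runs [simulate_genome_and_models()], [simulate_psms()] and
#' [simulate_domains()] under one seed.
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory, or `NULL`
#' @return list: `sim`, `psm`, `dom` (the three generators' outputs)
#' @export
simulate_study <- function(cfg = sim_config(), out_dir = NULL) {
  sim <- simulate_genome_and_models(cfg, out_dir)
  psm <- simulate_psms(sim, cfg, out_dir)
  dom <- simulate_domains(sim, cfg, out_dir)
  list(sim = sim, psm = psm, dom = dom)
}
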