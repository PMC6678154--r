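test_that("sim_config validates proportions and seed", {
  expect_error(sim_config(frac_lncrna_coding = 1.5), "in \\[0,1\\]")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("degenerate configs produce the promised truth tables", {
  cfg0 <- sim_config(seed = 3L, n_genes = 12L, n_lncrnas = 8L,
                     frac_isoform_nmd = 0)
  s0 <- simulate_genome_and_models(cfg0)
  expect_equal(sum(s0$truth$nmd), 0L)

  cfg1 <- sim_config(seed = 3L, n_genes = 6L, n_lncrnas = 10L,
                     frac_lncrna_coding = 1)
  s1 <- simulate_genome_and_models(cfg1)
  lnc <- s1$truth[s1$truth$type == "lncrna"]
  expect_true(all(lnc$coding))
  expect_true(all(lnc$protein_len >= 101L))
})

test_that("every emitted sequence has exactly one truth row", {
  st <- small_study()
  tr <- st$sim$truth
  expect_false(anyDuplicated(tr$id) > 0L)
  expect_setequal(tr$id[tr$type != "lncrna"], names(st$sim$models))
  expect_setequal(tr$id[tr$type == "lncrna"], names(st$sim$lncrnas))
})

test_that("generation is hash-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5L, n_genes = 10L, n_lncrnas = 6L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  sim1 <- simulate_genome_and_models(cfg, d1)
  simulate_psms(sim1, cfg, d1); simulate_domains(sim1, cfg, d1)
  sim2 <- simulate_genome_and_models(cfg, d2)
  simulate_psms(sim2, cfg, d2); simulate_domains(sim2, cfg, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, sort(f1)))
  h2 <- tools::md5sum(file.path(d2, sort(f2)))
  expect_identical(unname(h1), unname(h2))
  # different seed changes the genome
  sim3 <- simulate_genome_and_models(sim_config(seed = 6L, n_genes = 10L,
                                                n_lncrnas = 6L))
  expect_false(identical(sim1$genome, sim3$genome))
})

test_that("in the strong-separation limit every target PSM is retained", {
  cfg <- sim_config(seed = 2L, n_genes = 15L, n_lncrnas = 5L,
                    decoy_score_shift = 1000)
  s <- simulate_genome_and_models(cfg)
  ps <- simulate_psms(s, cfg)
  psms <- data.table::rbindlist(ps$psms)
  f <- fdr_filter(psms, 0.01)
  # every true target survives the filter in the separable limit
  expect_equal(sum(f$accepted$truth_correct == 1L),
               sum(!psms$is_decoy & psms$truth_correct == 1L))
})

test_that("forced single-peptide proteins are never validated downstream", {
  st <- full_study()
  det <- st$detection
  singles <- det$protein_id[det$single_peptide == 1L & det$n_peptides <= 1L &
                              det$detected == 1L]
  validated <- st$groups$protein_id[st$groups$validated == 1L]
  expect_true(length(singles) > 0L)
  expect_length(intersect(singles, validated), 0L)
})

test_that("DE calls recover planted effects within preregistered bounds", {
  # Bounds derived a priori from the count-noise model (see the methods
  # vignette): log2-ratio noise SD ~ sqrt(2 (1/mu + 1/size)) / ln 2 ~ 1.5 at
  # mu ~ 17, size = 2, so median |error| ~ 1.0, sensitivity for planted
  # |lfc| >= 2 ~ 0.6 and specificity ~ 0.75. Preregistered: sens >= 0.45,
  # spec >= 0.65, median abs error <= 1.4.
  st <- full_study()
  m <- merge(st$quant, st$detection[, c("protein_id", "true_log2fc")],
             by = "protein_id")
  m <- m[m$call != "not_quantifiable"]
  true_de <- abs(m$true_log2fc) >= 2
  called <- m$call %in% c("up", "down")
  expect_gt(sum(true_de), 10L)
  expect_gte(sum(true_de & called) / sum(true_de), 0.45)
  expect_gte(sum(!true_de & !called) / sum(!true_de), 0.65)
  expect_lte(median(abs(m$log2fc - m$true_log2fc)), 1.4)
})

test_that("spectral counts track abundance x length (NSAF's rationale)", {
  st <- full_study()
  det <- st$detection[st$detection$detected == 1L &
                        st$detection$source == "annotated"]
  g <- st$groups[st$groups$source == "annotated"]
  m <- merge(det, g[, c("protein_id", "length_aa")], by = "protein_id")
  psms <- data.table::fread(file.path(st$sim_dir, "psms_seedling.tsv"))
  spc <- psms[psms$truth_correct == 1L,
              list(spc = sum(spectral_count)), by = "protein_candidates"]
  m <- merge(m, spc, by.x = "protein_id", by.y = "protein_candidates")
  # the NB mean is abundance * L; with dispersion 0.5 the log-log
  # correlation against realized totals is strong but not 1
  expect_gt(cor(log(m$spc), log(m$abundance_seedling * m$length_aa)), 0.4)
})
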