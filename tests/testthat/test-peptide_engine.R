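test_that("digest follows the trypsin rule with KP suppression", {
  expect_setequal(digest("AAAKGGGRCCC", 0L, 3L, 50L),
                  c("AAAK", "GGGR", "CCC"))
  expect_setequal(digest("AAAKPGGG", 0L, 3L, 50L), "AAAKPGGG")
  expect_setequal(digest("AAAKPGGG", 0L, 3L, 50L, suppress_proline = FALSE),
                  c("AAAK", "PGGG"))
  expect_identical(digest("", 2L), character())
  # missed cleavages add the concatenated products
  expect_setequal(digest("AAAKGGGRCCC", 1L, 3L, 50L),
                  c("AAAK", "GGGR", "CCC", "AAAKGGGR", "GGGRCCC"))
  # case-insensitive
  expect_identical(digest("aaakgggrccc", 0L, 3L, 50L),
                   digest("AAAKGGGRCCC", 0L, 3L, 50L))
})

test_that("digest equals a brute-force enumerator on random proteins", {
  set.seed(99)
  for (i in 1:100) {
    p <- random_protein(sample(15:60, 1L))
    mc <- sample(0:2, 1L)
    lo <- sample(c(1L, 5L, 7L), 1L); hi <- sample(c(20L, 50L), 1L)
    expect_identical(digest(p, mc, lo, hi), brute_digest(p, mc, lo, hi),
                     info = paste("protein", i))
  }
})

test_that("reverse_decoy reverses sequences and doubles the database", {
  db <- c(p1 = "MKR", p2 = "ADA")
  td <- reverse_decoy(db)
  expect_length(td, 4L)
  expect_identical(td[["DECOY_p1"]], "RKM")
  expect_identical(td[["DECOY_p2"]], "ADA")   # palindrome: same sequence
  expect_error(reverse_decoy(td), "DECOY_")
})

test_that("decoy peptide lengths are distributed like target lengths", {
  set.seed(4)
  db <- setNames(vapply(1:60, function(i) random_protein(sample(120:300, 1L)),
                        ""), paste0("p", 1:60))
  td <- reverse_decoy(db)
  tl <- nchar(unlist(lapply(db, digest, 0L, 7L, 50L), use.names = FALSE))
  dl <- nchar(unlist(lapply(td[startsWith(names(td), "DECOY_")],
                            digest, 0L, 7L, 50L), use.names = FALSE))
  bins <- cut(c(tl, dl), breaks = c(6, 10, 15, 20, 30, 50))
  tab <- table(bins, rep(c("t", "d"), c(length(tl), length(dl))))
  expect_gt(suppressWarnings(stats::chisq.test(tab))$p.value, 1e-3)
})

test_that("fdr_filter handles separable and degenerate cases", {
  psms <- data.table::data.table(
    score = c(rep(10, 100), 5), is_decoy = c(rep(FALSE, 100), TRUE))
  r <- fdr_filter(psms, 0.01)
  expect_equal(nrow(r$accepted), 100L)
  expect_true(r$cutoff > 5 && r$cutoff <= 10)

  inverted <- data.table::data.table(score = c(10, 9, 1, 2),
                                     is_decoy = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(fdr_filter(inverted, 0.01), "no identifications")
})

test_that("fdr_filter acceptance is monotone in the threshold", {
  set.seed(21)
  for (i in 1:10) {
    psms <- data.table::data.table(
      score = c(rnorm(300, 5), rnorm(40, 2)),
      is_decoy = rep(c(FALSE, TRUE), c(300, 40)),
      id = seq_len(340))
    acc <- lapply(c(0.01, 0.05, 0.2), function(t)
      tryCatch(fdr_filter(psms, t)$accepted$id, error = function(e) integer()))
    expect_true(all(acc[[1L]] %in% acc[[2L]]))
    expect_true(all(acc[[2L]] %in% acc[[3L]]))
  }
})

test_that("match_peptides collapses I/L and ranks uniqueness", {
  dbs <- list(
    annotated = c(gA.p1 = "MMMNLEKMMMR", gB.p1 = "WWWTTTKWWW"),
    lncrna_orf = c(lnc1.orf1 = "CCCDDDKEEEK"),
    isoform_orf = c(tx_gA_1.orf1 = "MMMNLEKYYYR"))
  pg <- c(gA.p1 = "gA", gB.p1 = "gB", lnc1.orf1 = "lnc1",
          tx_gA_1.orf1 = "gA")
  acc <- data.table::data.table(
    peptide = c("NIEK",      # I/L: hits gA annotated + gA isoform
                "DDDK",      # only the lncRNA ORF
                "TTTK",      # only gB
                "QQQQQQK"),  # nowhere
    score = c(9, 8, 7, 6), sample = "s1", spectral_count = c(4L, 3L, 2L, 1L))
  ev <- match_peptides(acc, dbs, pg)
  ev <- ev[match(c("NLEK", "DDDK", "TTTK", "QQQQQQK"), ev$peptide_key)]
  expect_identical(ev$uniqueness,
                   c("gene_unique", "isoform_unique", "gene_unique",
                     "unmapped"))
  expect_setequal(ev$mapped_proteins[[1L]], c("gA.p1", "tx_gA_1.orf1"))
  # a peptide in both an annotated protein and a lncRNA ORF is shared
  dbs2 <- list(annotated = c(gA.p1 = "AAANLEKAAA"),
               lncrna_orf = c(lnc1.orf1 = "CCCNLEKCCC"))
  ev2 <- match_peptides(acc[1L], dbs2,
                        c(gA.p1 = "gA", lnc1.orf1 = "lnc1"))
  expect_identical(ev2$uniqueness, "shared")
})

test_that("infer_proteins applies the two-peptide and isoform-unique rules", {
  dbs <- list(
    annotated = c(gA.p1 = "AAAAAAKCCCCCCKDDDDDDK"),
    lncrna_orf = c(lnc1.orf1 = "EEEEEEKFFFFFFK"),
    isoform_orf = c(tx1.orf1 = "AAAAAAKCCCCCCK", tx2.orf1 = "AAAAAAKCCCCCCK"))
  pg <- c(gA.p1 = "gA", lnc1.orf1 = "lnc1", tx1.orf1 = "gA", tx2.orf1 = "gA")
  acc <- data.table::data.table(
    peptide = c("AAAAAAK", "CCCCCCK", "EEEEEEK"),
    score = c(9, 8, 7), sample = "s1",
    spectral_count = c(500L, 3L, 500L))
  ev <- match_peptides(acc, dbs, pg)
  gr <- infer_proteins(ev, min_peptides = 2L,
                       protein_lengths = c(gA.p1 = 21L, lnc1.orf1 = 14L,
                                           tx1.orf1 = 14L, tx2.orf1 = 14L),
                       protein_gene = pg)
  gr <- gr[match(c("gA.p1", "lnc1.orf1", "tx1.orf1", "tx2.orf1"),
                 gr$protein_id)]
  # gene validated on 2 shared-within-gene peptides
  expect_true(gr$validated[1L])
  # 1 peptide at SpC 500: the rule counts peptides, not spectra
  expect_false(gr$validated[2L])
  # two isoforms sharing all peptides: neither individually validated
  expect_false(any(gr$validated[3:4]))
})

test_that("SpC is conserved from accepted PSM rows into evidence", {
  st <- small_study()
  psms <- data.table::rbindlist(st$psm$psms)
  f <- fdr_filter(psms, 0.01)
  ev <- match_peptides(f$accepted, st$psm$databases)
  spc_ev <- sum(unlist(ev$samples))
  expect_identical(spc_ev, sum(f$accepted$spectral_count))
})
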