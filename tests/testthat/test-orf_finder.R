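test_that("find_orfs handles hand-checkable cases", {
  r <- find_orfs("ATGAAATAG", min_aa = 1L)
  expect_equal(nrow(r), 1L)
  expect_identical(r$protein_seq, "MK")
  expect_true(r$has_stop)
  expect_equal(r$start_nt, 0L)
  expect_equal(r$stop_nt, 9L)
  expect_equal(r$length_aa, 2L)

  expect_equal(nrow(find_orfs("CCCAAACCCAAA", min_aa = 1L)), 0L)  # no ATG
  expect_equal(nrow(find_orfs("", min_aa = 1L)), 0L)

  # nested ORFs sharing a stop collapse to the most 5' ATG
  r2 <- find_orfs("ATGATGAAATAG", min_aa = 1L)
  expect_equal(nrow(r2), 1L)
  expect_identical(r2$protein_seq, "MMK")

  # open ORF: no stop before the end
  r3 <- find_orfs("CCATGAAAAAA", min_aa = 1L)
  expect_false(r3$has_stop[1L])
  expect_identical(r3$protein_seq[1L], "MKK")
})

test_that("N codons translate to X and do not terminate", {
  r <- find_orfs("ATGTNAAAAA", min_aa = 1L)   # codon 2 = TNA -> X, not stop
  expect_identical(r$protein_seq[1L], "MXK")
  expect_false(r$has_stop[1L])
})

test_that("find_orfs equals the brute-force scanner on random sequences", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_dna_str(2000L)
    min_aa <- sample(c(1L, 10L, 50L), 1L)
    mine <- find_orfs(s, min_aa = min_aa)
    ref <- brute_orfs(s, min_aa)
    expect_equal(nrow(mine), nrow(ref), info = paste("seq", i))
    if (nrow(mine)) {
      expect_equal(mine$start_nt, ref$start_nt, info = paste("seq", i))
      expect_equal(mine$stop_nt, ref$stop_nt)
      expect_equal(mine$length_aa, ref$length_aa)
      expect_equal(mine$has_stop, ref$has_stop)
    }
  }
})

test_that("frame consistency: re-translating the ORF span reproduces it", {
  set.seed(5)
  for (i in 1:10) {
    s <- random_dna_str(1500L)
    orfs <- find_orfs(s, min_aa = 5L)
    for (k in seq_len(nrow(orfs))) {
      span <- substr(s, orfs$start_nt[k] + 1L, orfs$stop_nt[k])
      aa <- translate_nt(span)
      if (orfs$has_stop[k])
        expect_identical(aa, paste0(orfs$protein_seq[k], "*"))
      else
        expect_identical(aa, orfs$protein_seq[k])
    }
  }
})

test_that("translate_database applies the strict >100 aa lncRNA filter", {
  mk <- function(n_aa) paste0(
    "ATG",
    paste(rep("GCT", n_aa - 1L), collapse = ""), "TAA")
  seqs <- c(lnc100 = mk(100L), lnc101 = mk(101L))
  db <- translate_database(seqs, "lncrna")
  expect_identical(names(db$proteins), "lnc101.orf1")   # 100 aa excluded
  expect_equal(db$orf_table$length_aa, 101L)
  # same sequences as isoforms with min_aa = 100: both kept
  db2 <- translate_database(seqs, "isoform", min_aa = 100L)
  expect_equal(nrow(db2$orf_table), 2L)
})

test_that("translate_database keeps multiple non-nested ORFs per transcript", {
  # codon bodies chosen so no shifted-frame ATG creates a third ORF
  two <- paste0("ATG", paste(rep("GCT", 100L), collapse = ""), "TAA",
                "CCC",
                "ATG", paste(rep("GAA", 110L), collapse = ""), "TAA")
  db <- translate_database(c(tx1 = two), "isoform", min_aa = 100L)
  expect_equal(nrow(db$orf_table), 2L)
  expect_identical(db$orf_table$orf_id, c("tx1.orf1", "tx1.orf2"))
  # sorted by length: the 111-aa ORF first
  expect_equal(db$orf_table$length_aa, c(111L, 101L))
  expect_error(translate_database(c(a = "ATG", a = "ATG"), "isoform"),
               "duplicate")
})

test_that("find_orfs output is deterministic and order-stable", {
  s <- random_dna_str(3000L)
  expect_identical(find_orfs(s, 10L), find_orfs(s, 10L))
})
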