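mk_groups <- function(spc_a, spc_b, L, npep_a = 2L, npep_b = 2L) {
  n <- length(spc_a)
  data.table::data.table(
    protein_id = paste0("p", seq_len(n)), gene_id = paste0("g", seq_len(n)),
    source = "annotated", n_distinct_peptides = pmax(npep_a, npep_b),
    n_unique_peptides = 0L, best_score = 10, validated = TRUE,
    length_aa = L,
    peptides = replicate(n, list("X")),
    spc_per_sample = lapply(seq_len(n), function(i)
      list(a = spc_a[i], b = spc_b[i])),
    npep_per_sample = lapply(seq_len(n), function(i)
      list(a = npep_a[min(i, length(npep_a))],
           b = npep_b[min(i, length(npep_b))])))
}

test_that("nsaf normalizes as defined", {
  expect_equal(nsaf(5L, 100L)$nsaf, 1)                      # single protein
  r <- nsaf(c(10L, 5L), c(100L, 50L))                       # equal SpC/L
  expect_equal(r$nsaf, c(0.5, 0.5))
  expect_error(nsaf(c(0L, 0L), c(10L, 10L)), "nothing quantified")
  expect_error(nsaf(5L, 0L), "positive")
})

test_that("nsaf sums to one and is invariant to uniform SpC scaling", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:40, 1L)
    spc <- rpois(n, 20) + 1L
    L <- sample(100:500, n, replace = TRUE)
    r <- nsaf(spc, L)
    expect_equal(sum(r$nsaf), 1, tolerance = 1e-9)
    expect_equal(nsaf(spc * 7L, L)$nsaf, r$nsaf, tolerance = 1e-12)
  }
})

test_that("fold-change boundary is inclusive at 4 (pseudocounted)", {
  # engineered so pseudocounted NSAF ratio for p1 is exactly 4
  g <- mk_groups(spc_a = c(3L, 24L), spc_b = c(15L, 15L), L = c(100L, 100L))
  q <- quantify_proteins(g, "a", "b")
  expect_equal(q$fc[1L], 4)
  expect_identical(q$call[1L], "up")
  expect_equal(sum(q$nsaf_a), 1)         # reported NSAF is pseudocount-free
})

test_that("zero SpC in one sample yields a finite pseudocounted call", {
  g <- mk_groups(spc_a = c(0L, 10L), spc_b = c(30L, 10L), L = c(200L, 200L))
  q <- quantify_proteins(g, "a", "b")
  expect_true(is.finite(q$fc[1L]))
  expect_identical(q$call[1L], "up")
})

test_that("not_quantifiable requires failing the peptide rule in both samples", {
  g <- mk_groups(spc_a = c(9L, 10L), spc_b = c(9L, 10L), L = c(100L, 100L),
                 npep_a = c(1L, 2L), npep_b = c(1L, 2L))
  q <- quantify_proteins(g, "a", "b")
  expect_identical(q$call[1L], "not_quantifiable")
  expect_identical(q$call[2L], "unchanged")
})

test_that("direction duality: swapping samples swaps up and down", {
  set.seed(13)
  g <- mk_groups(spc_a = rpois(15, 12), spc_b = rpois(15, 12),
                 L = sample(150:400, 15, replace = TRUE))
  ab <- quantify_proteins(g, "a", "b")
  ba <- quantify_proteins(g, "b", "a")
  expect_equal(ab$fc, 1 / ba$fc, tolerance = 1e-12)
  expect_identical(ab$call == "up", ba$call == "down")
  expect_identical(ab$call == "down", ba$call == "up")
})

test_that("nsaf is monotone in a protein's own SpC", {
  g1 <- mk_groups(spc_a = c(10L, 10L, 10L), spc_b = c(1L, 1L, 1L),
                  L = c(100L, 100L, 100L))
  g2 <- mk_groups(spc_a = c(20L, 10L, 10L), spc_b = c(1L, 1L, 1L),
                  L = c(100L, 100L, 100L))
  qa1 <- quantify_proteins(g1, "a", "b")$nsaf_a
  qa2 <- quantify_proteins(g2, "a", "b")$nsaf_a
  expect_gt(qa2[1L], qa1[1L])
  expect_true(all(qa2[-1L] <= qa1[-1L]))
})

test_that("differential summarizes counts consistently", {
  g <- mk_groups(spc_a = c(2L, 40L, 10L), spc_b = c(40L, 2L, 10L),
                 L = c(100L, 100L, 100L))
  de <- differential(quantify_proteins(g, "a", "b"))
  expect_equal(de$n_total_de, de$n_up + de$n_down)
  expect_equal(de$n_up, 1L)
  expect_equal(de$n_down, 1L)
})

test_that("sample_correlation behaves on canonical inputs", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(sample_correlation(x, x), 1)
  expect_equal(sample_correlation(x, 3 * x), 1)        # scale invariance
  y <- rev(x)
  direct <- cor(log10(x), log10(y))
  expect_equal(sample_correlation(x, y), direct)
  expect_lt(sample_correlation(x, y), 0)
  expect_equal(sample_correlation(x, y, method = "spearman"), -1)
  expect_error(sample_correlation(c(1, 2), c(1, 2)), "fewer than 3")
  expect_error(sample_correlation(c(1, 0, 0, 1), c(1, 1, 0, 0)),
               "fewer than 3")
})
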