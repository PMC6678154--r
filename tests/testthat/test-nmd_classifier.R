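mk_model <- function(widths, strand = "+") {
  # lay exons on a fake chromosome with 10-nt introns
  starts <- integer(length(widths)); ends <- integer(length(widths))
  pos <- 1L
  for (k in seq_along(widths)) {
    starts[k] <- pos; ends[k] <- pos + widths[k] - 1L
    pos <- ends[k] + 11L
  }
  ord <- if (strand == "+") seq_along(widths) else rev(seq_along(widths))
  transcript_model("tx", "g", "chr1", strand,
                   cbind(starts[ord], ends[ord]), biotype = "isoform")
}
mk_orf <- function(stop_nt, has_stop = TRUE, start_nt = 0L)
  list(orf_id = "tx.orf1", start_nt = start_nt, stop_nt = stop_nt,
       has_stop = has_stop)

test_that("classify_nmd implements the 50-nt last-junction rule", {
  # single exon: no junction, never NMD
  r <- classify_nmd(mk_model(300L), mk_orf(90L))
  expect_false(r$is_nmd)

  # two exons 200 + 100, stop ending at 150: d = 200 - 150 = 50 -> NMD
  r <- classify_nmd(mk_model(c(200L, 100L)), mk_orf(150L))
  expect_equal(r$last_junction_pos, 200L)
  expect_equal(r$d, 50L)
  expect_true(r$is_nmd)

  # boundary below: d = 49 is not NMD
  expect_false(classify_nmd(mk_model(c(200L, 100L)), mk_orf(151L))$is_nmd)
  # stop downstream of the last junction: d < 0, not NMD
  expect_false(classify_nmd(mk_model(c(200L, 100L)), mk_orf(240L))$is_nmd)
  # open ORF (no stop codon): not NMD
  expect_false(classify_nmd(mk_model(c(200L, 100L)),
                            mk_orf(150L, has_stop = FALSE))$is_nmd)
  # inconsistent inputs
  expect_error(classify_nmd(mk_model(c(200L, 100L)), mk_orf(400L)),
               "inconsistent")
  # strand does not matter once in mature coordinates: a minus-strand model
  # with transcript-order widths 200 + 100 (genomic layout reversed)
  minus <- transcript_model("tx", "g", "chr1", "-",
                            cbind(c(111L, 1L), c(310L, 100L)),
                            biotype = "isoform")
  expect_true(classify_nmd(minus, mk_orf(150L))$is_nmd)
})

test_that("NMD threshold is monotone", {
  st <- full_study()
  calls50 <- st$nmd_calls
  models <- read_gff3(file.path(st$sim_dir, "models.gff3"))
  genome <- read_fasta_nt(file.path(st$sim_dir, "genome.fasta"))
  for (id in names(models))
    models[[id]]$spliced_seq <- spliced_sequence(models[[id]], genome)
  iso <- names(models)[vapply(models, `[[`, "", "biotype") == "isoform"]
  seqs <- setNames(vapply(models[iso], `[[`, "", "spliced_seq"), iso)
  db <- translate_database(seqs, "isoform", min_aa = 100L)
  for (th in c(80L, 150L)) {
    calls_hi <- classify_nmd_set(models, db$orf_table, th)
    hi_set <- calls_hi$transcript_id[calls_hi$is_nmd]
    lo_set <- calls50$transcript_id[calls50$is_nmd == 1L]
    expect_true(all(hi_set %in% lo_set))
  }
})

test_that("nmd_composition reports round-half-up percentages", {
  calls <- data.table::data.table(transcript_id = paste0("t", 1:8),
                                  is_nmd = rep(c(TRUE, FALSE), c(0L, 8L)))
  expect_equal(nmd_composition(calls)$percent, 0)
  calls$is_nmd[1:3] <- TRUE
  expect_equal(nmd_composition(calls)$percent, 37.5)
  expect_equal(nmd_composition(calls, subset = paste0("t", 1:4))$percent, 75)
  expect_error(nmd_composition(calls, subset = "absent"), "empty")
})
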