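# Shared fixtures, built once per test session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# the default-scale study (generator defaults, seed 1) plus a full pipeline
# run over it; used by most truth-recovery tests
full_study <- function() {
  memo("full", function() {
    dir <- file.path(tempdir(), "pgx_full_study")
    res <- pgx_cli(c("run-all", "--simulate", "--seed", "1",
                     "--out-dir", dir))
    sim_dir <- file.path(dir, "inputs")
    list(dir = dir, sim_dir = sim_dir, res = res,
         truth = data.table::fread(file.path(sim_dir, "truth.tsv")),
         detection = data.table::fread(file.path(sim_dir,
                                                 "detection_truth.tsv")),
         quant = data.table::fread(file.path(dir, "quant.tsv")),
         groups = data.table::fread(file.path(dir, "protein_groups.tsv")),
         nmd_calls = data.table::fread(file.path(dir, "nmd_calls.tsv")))
  })
}

# a small study kept in memory (no files) for cheap structural tests
small_study <- function() {
  memo("small", function() {
    cfg <- sim_config(seed = 7L, n_genes = 25L, n_lncrnas = 12L)
    simulate_study(cfg, out_dir = NULL)
  })
}

random_protein <- function(n) {
  paste(sample(names(pgxpipe:::AVG_RESIDUE_MASS), n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force tryptic digestion: enumerate every substring whose boundaries
# are cleavage sites (or termini) and whose internal cleavage-site count is
# within the missed-cleavage budget
brute_digest <- function(seq, mc, min_len, max_len) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) return(character())
  res <- strsplit(seq, "")[[1L]]
  is_cut <- res %in% c("K", "R") &
    c(res[-1L] != "P", FALSE)            # KP/RP suppression, none after end
  cuts <- c(0L, which(is_cut[-n]), n)    # legal boundaries (0-based)
  cuts <- sort(unique(cuts))
  out <- character()
  for (i in seq_along(cuts)) for (j in seq_along(cuts)) {
    if (cuts[j] <= cuts[i]) next
    inner <- sum(cuts > cuts[i] & cuts < cuts[j])
    len <- cuts[j] - cuts[i]
    if (inner <= mc && len >= min_len && len <= max_len)
      out <- c(out, substr(seq, cuts[i] + 1L, cuts[j]))
  }
  sort(unique(out))
}

# brute-force ORF scan: walk every ATG in every frame to its stop, reduce to
# the longest ORF per (frame, stop), filter by length
brute_orfs <- function(seq, min_aa) {
  n <- nchar(seq)
  hits <- list()
  for (frame in 0:2) {
    pos <- frame
    while (pos + 3L <= n) {
      if (substr(seq, pos + 1L, pos + 3L) == "ATG") {
        q <- pos
        stop_at <- NA_integer_
        while (q + 3L <= n) {
          cod <- substr(seq, q + 1L, q + 3L)
          if (cod %in% c("TAA", "TAG", "TGA")) { stop_at <- q; break }
          q <- q + 3L
        }
        if (!is.na(stop_at)) {
          key <- paste(frame, stop_at)
          len <- (stop_at - pos) / 3
          if (is.null(hits[[key]]) || hits[[key]]$start > pos)
            hits[[key]] <- list(frame = frame, start = pos,
                                stop_end = stop_at + 3L, len = len,
                                has_stop = TRUE)
        } else {
          last_full <- pos + 3L * ((n - pos) %/% 3L)
          key <- paste(frame, "open")
          len <- (last_full - pos) / 3
          if (is.null(hits[[key]]) || hits[[key]]$start > pos)
            hits[[key]] <- list(frame = frame, start = pos,
                                stop_end = last_full, len = len,
                                has_stop = FALSE)
        }
      }
      pos <- pos + 3L
    }
  }
  keep <- Filter(function(h) h$len >= min_aa, hits)
  df <- do.call(rbind, lapply(keep, function(h)
    data.frame(frame = h$frame, start_nt = h$start, stop_nt = h$stop_end,
               length_aa = h$len, has_stop = h$has_stop)))
  if (is.null(df)) return(data.frame(frame = integer(), start_nt = integer(),
                                     stop_nt = integer(),
                                     length_aa = integer(),
                                     has_stop = logical()))
  df[order(-df$length_aa, df$start_nt), , drop = FALSE]
}
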