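pair_tbl <- function(fwd, rev, id = sprintf("r%03d", seq_along(fwd))) {
  tibble::tibble(read_id = id, fwd_seq = fwd, rev_seq = rev)
}

test_that("demultiplex assigns by exact forward-prefix match and trims both mates", {
  bt <- tibble::tibble(sample_id = c("S1", "S2"), barcode = c("ACGT", "TTTT"))
  pairs <- pair_tbl(
    fwd = c("ACGTAAAACCCC", "ACGNAAAACCCC", "TTTTGGGG", "GGGGAAAA"),
    rev = c("ACGTCCCCAAAA", "ACGTCCCCAAAA", "TTTTCCCC", "GGGGTTTT")
  )
  d <- demultiplex(pairs, bt)
  expect_equal(d$sample_id, c("S1", "S2"))
  expect_equal(d$fwd_seq, c("AAAACCCC", "GGGG"))
  expect_equal(d$rev_seq, c("CCCCAAAA", "CCCC"))
  expect_equal(attr(d, "n_unassigned"), 2L)

  expect_error(demultiplex(pairs, bt[0, ]), "empty")
  expect_error(demultiplex(pairs, tibble::tibble(
    sample_id = c("a", "b"), barcode = c("ACGT", "ACGT"))), "[Dd]uplicate")
})

test_that("join_mates concatenates with the reverse complement", {
  expect_equal(join_mates("ACGT", "AAAA"), "ACGTTTTT")
  expect_equal(join_mates("", ""), "")
  x <- random_keys(5, width = 30)
  expect_equal(join_mates(x, revcomp(x)), paste0(x, x))
  expect_equal(join_mates("ACGN", "NA"), "ACGNTN")
  expect_error(join_mates("ACGU", "AAAA"), "non-nucleotide")
})

test_that("extraction applies the positional flank rule with ordered rejection reasons", {
  lw <- "TCCGACCTAGGTTGAGAA"
  rw <- "ATGGCACAAGTTTGGACT"
  ex <- extract_synes(pair_tbl(lw, revcomp(rw)))
  expect_true(is.na(ex$reason))
  expect_equal(ex$left_core, "GACCTAGGTTGA")
  expect_equal(ex$right_core, "GCACAAGTTTGG")
  expect_equal(ex$key, "GACCTAGGTTGAGCACAAGTTTGG")

  # padding before the last-18 window never changes the result
  ex_pad <- extract_synes(pair_tbl(paste0("GGGGGGGG", lw),
                                   revcomp(paste0(rw, "CCCCCCCC"))))
  expect_equal(ex_pad$key, ex$key)

  bad <- extract_synes(pair_tbl(
    fwd = c("TCAGACCTAGGTTGAGAA",  # TCC flank violated
            "TCCGACCTAGGTNGAGAA",  # N inside the left core
            lw,                    # right flank violated (below)
            "TNCGACCTAGGTTGAGAA",  # N in a flank -> flank failure
            "TCCGACC"),            # too short
    rev = c(revcomp(rw), revcomp(rw), revcomp("ATGGCACAAGTTTGGACG"),
            revcomp(rw), revcomp(rw))
  ))
  expect_equal(bad$reason, c("flank_left", "ambiguous_base", "flank_right",
                             "flank_left", "too_short"))
  expect_true(all(is.na(bad$key)))
})

test_that("tally builds a sorted non-redundant table with consistent bookkeeping", {
  x <- strrep("A", 24)
  y <- paste0(strrep("C", 12), strrep("G", 12))
  ex <- tibble::tibble(key = c(x, x, y), reason = NA_character_)
  cs <- tally_synes(ex, "S1", n_raw = 5)
  expect_s3_class(cs, "counted_sample")
  expect_equal(cs$key, c(x, y))
  expect_equal(cs$count, c(2L, 1L))
  expect_equal(attr(cs, "n_filtered"), 3L)
  expect_equal(attr(cs, "n_unique"), 2L)
  expect_equal(attr(cs, "n_raw"), 5L)
  expect_equal(glance(cs)$pct_unique, 66.7)
  expect_error(tally_synes(ex, "S1", n_raw = 2), "n_raw")

  empty <- tally_synes(tibble::tibble(key = character(),
                                      reason = character()), "S0", 0)
  expect_equal(attr(empty, "n_filtered"), 0L)
})

test_that("percent-unique reproduces the published worked examples", {
  expect_equal(pct_unique(234498, n_filtered = 259149), 90.5)
  expect_equal(pct_unique(82834, n_filtered = 299152), 27.7)
  expect_equal(pct_unique(100, n_filtered = 100), 100.0)
  expect_error(pct_unique(0, n_filtered = 0), "undefined")
})

test_that("pipeline conservation: assigned = accepted + rejections by reason", {
  cfg <- two_sample_config(n_elements = 300, depth = 2000,
                           error_rate = 0.05, n_rate = 0.01, seed = 21)
  sim <- simulate_screen(cfg)
  d <- demultiplex(sim$reads[c("read_id", "fwd_seq", "rev_seq")],
                   cfg$barcode_table)
  ex <- extract_synes(d[d$sample_id == "REF", ])
  rs <- rejection_summary(ex)
  expect_equal(sum(rs$n), nrow(ex))
  expect_equal(rs$n[rs$reason == "accepted"], sum(is.na(ex$reason)))
  expect_true(all(rs$n[rs$reason %in% c("flank_left", "flank_right",
                                        "ambiguous_base")] > 0))
})

test_that("zero-noise simulation round-trips exactly through the tally", {
  cfg <- two_sample_config(n_elements = 400, depth = 3000, seed = 13)
  sim <- simulate_screen(cfg)
  d <- demultiplex(sim$reads[c("read_id", "fwd_seq", "rev_seq")],
                   cfg$barcode_table)
  expect_equal(attr(d, "n_unassigned"), 0L)
  for (sid in c("REF", "CHIP")) {
    ds <- d[d$sample_id == sid, ]
    expect_equal(nrow(ds), 3000L)
    cs <- tally_synes(extract_synes(ds), sid, n_raw = nrow(ds))
    truth <- sim$truth[sim$truth$sample_id == sid, ]
    got <- tidy(cs)[c("key", "count")] |> dplyr::arrange(key)
    want <- tibble::tibble(key = truth$element_key, count = truth$count) |>
      dplyr::arrange(key)
    expect_equal(got, want)
  }
})

test_that("counts tables round-trip through TSV", {
  cfg <- two_sample_config(n_elements = 50, depth = 300, seed = 8)
  sim <- simulate_screen(cfg)
  d <- demultiplex(sim$reads[c("read_id", "fwd_seq", "rev_seq")],
                   cfg$barcode_table)
  cs <- tally_synes(extract_synes(d[d$sample_id == "REF", ]), "REF", 300)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cs, path)
  back <- read_counts(path, "REF", n_raw = 300)
  expect_equal(tidy(back), tidy(cs))
  expect_equal(attr(back, "n_unique"), attr(cs, "n_unique"))
})
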