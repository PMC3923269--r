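make_counted <- function(keys, counts, sample_id = "T") {
  tally_synes(tibble::tibble(key = rep(keys, counts),
                             reason = NA_character_),
              sample_id, n_raw = sum(counts))
}

test_that("count_kmers counts windows within each core separately", {
  cs <- make_counted(paste0(strrep("A", 12), strrep("C", 12)), 1L)
  k12 <- count_kmers(cs, 12)
  expect_equal(attr(k12, "total"), 2L)
  expect_setequal(k12$kmer, c(strrep("A", 12), strrep("C", 12)))

  k6 <- count_kmers(cs, 6)
  expect_equal(k6$count[k6$kmer == "AAAAAA"], 7L)
  expect_equal(k6$count[k6$kmer == "CCCCCC"], 7L)
  expect_equal(nrow(k6), 2L)  # no window spans the core boundary

  withr::with_seed(3, keys <- random_keys(10))
  cs10 <- make_counted(keys, rep(1L, 10))
  for (k in c(5L, 6L, 7L)) {
    expect_equal(attr(count_kmers(cs10, k), "total"), 2L * (13L - k) * 10L)
  }
  expect_error(count_kmers(cs10, 0), "in \\[1, 12\\]")
  expect_error(count_kmers(cs10, 13), "in \\[1, 12\\]")
})

test_that("weighted counting multiplies by sequence counts", {
  withr::with_seed(4, keys <- random_keys(3))
  cs <- make_counted(keys, c(5L, 2L, 1L))
  kw <- count_kmers(cs, 5, weighted = TRUE)
  expect_equal(attr(kw, "total"), 2L * 8L * 8L)  # 2 cores x 8 windows x 8 reads
  ku <- count_kmers(cs, 5, weighted = FALSE)
  expect_equal(attr(ku, "total"), 2L * 8L * 3L)
})

test_that("enrichment ratios match hand arithmetic and rank deterministically", {
  s <- manual_kmer_table(c(AAAAA = 8, CCCCC = 8), k = 5)
  r <- manual_kmer_table(c(AAAAA = 4, CCCCC = 12), k = 5)
  er <- enrichment_ratio(s, r, pseudocount = 0)
  expect_equal(er$ratio[er$kmer == "AAAAA"], 2.0)
  expect_equal(er$ratio[er$kmer == "CCCCC"], 2 / 3)
  expect_equal(er$kmer, c("AAAAA", "CCCCC"))  # ranked by ratio descending

  # identical tables: all ratios exactly 1 at any pseudocount
  er1 <- enrichment_ratio(s, s, pseudocount = 0)
  expect_true(all(er1$ratio == 1))
  er2 <- enrichment_ratio(s, s, pseudocount = 1)
  expect_true(all(er2$ratio == 1))

  expect_error(enrichment_ratio(s, manual_kmer_table(c(AAAAAA = 1), k = 6)),
               "different k")
  expect_error(enrichment_ratio(s, r, pseudocount = -1), ">= 0")
})

test_that("reference-absent k-mers are reported separately at pseudocount 0", {
  s <- manual_kmer_table(c(AAAAA = 6, GGGGG = 2), k = 5)
  r <- manual_kmer_table(c(AAAAA = 8), k = 5)
  er <- enrichment_ratio(s, r, pseudocount = 0)
  expect_false("GGGGG" %in% er$kmer)
  ra <- attr(er, "reference_absent")
  expect_equal(ra$kmer, "GGGGG")
  expect_equal(ra$count_sample, 2L)
  # with a pseudocount the same k-mer gets a finite ratio
  er1 <- enrichment_ratio(s, r, pseudocount = 1)
  expect_true(is.finite(er1$ratio[er1$kmer == "GGGGG"]))
})

test_that("ratios at pseudocount 0 are scale invariant", {
  withr::with_seed(12, keys <- random_keys(40))
  cs <- make_counted(keys, sample(1:9, 40, replace = TRUE))
  s <- count_kmers(cs, 5, weighted = TRUE)
  r <- count_kmers(cs, 5, weighted = FALSE)
  base <- enrichment_ratio(s, r, pseudocount = 0)
  scale_tab <- function(kt, c) {
    manual_kmer_table(stats::setNames(kt$count * c, kt$kmer), attr(kt, "k"),
                      total = attr(kt, "total") * c)
  }
  scaled <- enrichment_ratio(scale_tab(s, 7L), scale_tab(r, 7L),
                             pseudocount = 0)
  m <- match(base$kmer, scaled$kmer)
  expect_equal(scaled$ratio[m], base$ratio)
})

test_that("coupled partners are extracted with summed counts and reciprocity", {
  L1 <- strrep("A", 12); L2 <- strrep("C", 12)
  R1 <- strrep("G", 12); R2 <- strrep("T", 12)
  cs <- make_counted(c(paste0(L1, R1), paste0(L1, R2), paste0(L2, R1)),
                     c(3L, 1L, 5L))
  p <- coupled_partners(cs, L1, side = "left")
  expect_equal(p$partner_core, c(R1, R2))
  expect_equal(p$count, c(3L, 1L))
  expect_equal(nrow(coupled_partners(cs, strrep("T", 12), side = "left")), 0L)
  expect_error(coupled_partners(cs, "ACGT", side = "left"), "12-nt")

  # reciprocity on a random table
  withr::with_seed(6, keys <- random_keys(30))
  rcs <- make_counted(keys, sample(1:5, 30, replace = TRUE))
  for (i in 1:10) {
    L <- substr(keys[i], 1, 12)
    for (R in coupled_partners(rcs, L, side = "left")$partner_core) {
      expect_true(L %in% coupled_partners(rcs, R, side = "right")$partner_core)
    }
  }
})

test_that("MEME-input FASTA round-trips the partner multiset", {
  L1 <- strrep("A", 12)
  cs <- make_counted(c(paste0(L1, strrep("G", 12)),
                       paste0(L1, strrep("T", 12)),
                       paste0(L1, paste0(strrep("G", 6), strrep("T", 6)))),
                     c(4L, 2L, 1L))
  p <- coupled_partners(cs, L1, side = "left")
  path <- withr::local_tempfile(fileext = ".fasta")
  export_meme_fasta(p, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_length(back, 3L)
  expect_true(all(Biostrings::width(back) == 12L))
  expect_setequal(as.character(back), p$partner_core)
  expect_true(all(grepl(sprintf("^%s\\|left\\|\\d+\\|\\d+$", L1),
                        names(back))))
  empty <- coupled_partners(cs, strrep("C", 12), side = "left")
  expect_error(export_meme_fasta(empty, path), "no partner")
})
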