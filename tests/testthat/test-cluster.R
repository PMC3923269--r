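# Toy cluster fixture: A abundant, B a Hamming-1 mutant of A, C a
# Hamming-1 mutant of B (distance 2 from A), D unrelated.
toy_keys <- local({
  A <- strrep("A", 24)
  B <- A; substr(B, 1, 1) <- "C"
  C <- B; substr(C, 2, 2) <- "C"
  D <- strrep("G", 24)
  c(A = A, B = B, C = C, D = D)
})
toy_counts <- tibble::tibble(key = unname(toy_keys),
                             count = c(100L, 5L, 2L, 50L))

test_that("hamming_neighbors enumerates exactly the 72 distance-1 keys", {
  a24 <- strrep("A", 24)
  nb <- hamming_neighbors(a24)
  expect_length(nb, 72)
  expect_false(anyDuplicated(nb) > 0)
  expect_false(a24 %in% nb)
  expect_true(paste0("C", strrep("A", 23)) %in% nb)
  expect_error(hamming_neighbors("ACGT"), "24-nt")

  # symmetry against brute-force pairwise Hamming distance
  withr::with_seed(5, keys <- random_keys(100))
  for (i in 1:20) {
    a <- keys[i]
    d <- vapply(keys, function(b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, integer(1))
    expect_setequal(keys[d == 1L], intersect(hamming_neighbors(a), keys))
    for (b in keys[d == 1L]) expect_true(a %in% hamming_neighbors(b))
  }
})

test_that("build_clusters follows the frequency-guided parent rule on the toy set", {
  cl <- build_clusters(toy_counts)
  expect_s3_class(cl, "syne_clusters")
  expect_equal(attr(cl, "n_clusters"), 2L)
  ct <- cluster_table(cl)
  expect_equal(ct$root_key, c(toy_keys[["A"]], toy_keys[["D"]]))
  expect_equal(ct$cumulative, c(107L, 50L))
  expect_equal(ct$n_members, c(3L, 1L))
  # C's parent is B (its only distance-1 neighbour), giving a 2-level tree
  expect_equal(cl$parent_key[cl$key == toy_keys[["C"]]], toy_keys[["B"]])
  expect_equal(cl$root_key[cl$key == toy_keys[["C"]]], toy_keys[["A"]])
  oracle <- cluster_oracle(toy_counts)
  expect_identical(tidy(cl)[order(cl$key), ], oracle[order(oracle$key), ])
})

test_that("distance >= 2 keys and equal-count neighbours never merge", {
  withr::with_seed(30, keys <- random_keys(40))  # random 24-mers: d >= 2 w.h.p.
  tbl <- tibble::tibble(key = keys, count = sample(1:100, 40))
  cl <- build_clusters(tbl)
  expect_equal(attr(cl, "n_clusters"), 40L)
  expect_equal(pct_clustered(cl), 0.0)

  a <- strrep("A", 24)
  b <- a; substr(b, 3, 3) <- "T"
  cl2 <- build_clusters(tibble::tibble(key = c(a, b), count = c(7L, 7L)))
  expect_equal(attr(cl2, "n_clusters"), 2L)
})

test_that("clustering is an exact cover independent of input row order", {
  withr::with_seed(77, tbl <- random_cluster_table())
  cl1 <- build_clusters(tbl)
  cl2 <- build_clusters(tbl[sample(nrow(tbl)), ])
  expect_equal(tidy(cl1)[order(cl1$key), ], tidy(cl2)[order(cl2$key), ])
  # every key in exactly one cluster; cumulative sums to total count
  expect_setequal(cl1$key, tbl$key)
  expect_equal(sum(cluster_table(cl1)$cumulative), sum(tbl$count))
  expect_equal(attr(cl1, "n_filtered"), sum(tbl$count))
  # roots carry the maximum count of their cluster
  mx <- tapply(cl1$count, cl1$root_key, max)
  root_count <- cl1$count[match(names(mx), cl1$key)]
  expect_equal(as.vector(mx), root_count)
})

test_that("percent-clustered reproduces the published worked example", {
  expect_equal(pct_clustered(82834, n_clusters = 44055), 46.8)
  expect_equal(pct_clustered(4, n_clusters = 2), 50.0)
  expect_error(pct_clustered(0, n_clusters = 0), "undefined")
})

test_that("representatives are ranked by cumulative frequency", {
  cl <- build_clusters(toy_counts)
  expect_equal(representatives(cl, top_n = 1),
               tibble::tibble(root_key = toy_keys[["A"]], cumulative = 107L))
  expect_equal(nrow(representatives(cl, top_n = 0)), 2L)
  single <- build_clusters(tibble::tibble(key = toy_keys[["A"]], count = 3L))
  expect_equal(representatives(single),
               tibble::tibble(root_key = toy_keys[["A"]], cumulative = 3L))
})

test_that("common_representatives computes the exact Venn partition", {
  mk <- function(keys, id) {
    cl <- build_clusters(tibble::tibble(key = keys,
                                        count = seq_along(keys) + 1L))
    attr(cl, "sample_id") <- id
    cl
  }
  withr::with_seed(99, pool <- random_keys(50))
  s1 <- mk(sample(pool, 30), "X")
  s2 <- mk(sample(pool, 30), "Y")
  s3 <- mk(sample(pool, 30), "Z")
  venn <- common_representatives(list(X = s1, Y = s2, Z = s3))
  # brute-force set algebra over membership bitmasks
  reps <- list(X = s1$root_key, Y = s2$root_key, Z = s3$root_key)
  uni <- unique(unlist(reps))
  expect_equal(sum(venn$n_keys), length(uni))
  for (i in seq_len(nrow(venn))) {
    members <- strsplit(venn$samples[i], "&", fixed = TRUE)[[1]]
    expected <- uni[vapply(uni, function(k) {
      identical(sort(names(reps)[vapply(reps, function(r) k %in% r, logical(1))]),
                sort(members))
    }, logical(1))]
    expect_setequal(venn$keys[[i]], expected)
  }

  # disjoint and identical edge cases
  d1 <- mk(pool[1:5], "A1")
  d2 <- mk(pool[6:10], "A2")
  vd <- common_representatives(list(A1 = d1, A2 = d2))
  expect_false(any(vd$n_samples == 2))
  vi <- common_representatives(list(B1 = d1, B2 = d1))
  expect_equal(vi$n_keys[vi$samples == "B1&B2"], 5L)
  expect_error(common_representatives(list(d1)), "at least two")
})

test_that("enrichment raises percent-clustered over the unenriched library", {
  # enriched sampling concentrates reads on few elements whose sequencing
  # error halos then merge into clusters; in the unenriched library most
  # elements are too rare (count 1) to absorb their halo variants
  cfg <- two_sample_config(n_elements = 5000, depth = 4000, seed = 17,
                           error_rate = 0.01,
                           planted = tibble::tibble(pattern = "TTGACC",
                                                    fold = 100))
  sim <- simulate_screen(cfg)
  d <- demultiplex(sim$reads[c("read_id", "fwd_seq", "rev_seq")],
                   cfg$barcode_table)
  pc <- vapply(c("REF", "CHIP"), function(sid) {
    cs <- tally_synes(extract_synes(d[d$sample_id == sid, ]), sid,
                      n_raw = sum(d$sample_id == sid))
    pct_clustered(build_clusters(cs))
  }, double(1))
  expect_gte(pc[["CHIP"]], pc[["REF"]])
})
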