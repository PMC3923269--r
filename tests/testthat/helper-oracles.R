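# Independent oracles and random-input generators used across the suite.
# The oracles deliberately re-derive results by brute force, sharing no code
# with the package implementation.

random_keys <- function(n, width = 24L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              ncol = width)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# A random count table with planted Hamming-1 structure: base keys plus a
# few single-mismatch mutants each, including deliberate count ties.
random_cluster_table <- function(n_base = 60L, max_mutants = 4L) {
  base <- unique(random_keys(n_base))
  keys <- base
  counts <- sample(5:60, length(base), replace = TRUE)
  for (b in base) {
    for (j in seq_len(sample(0:max_mutants, 1))) {
      pos <- sample(24L, 1)
      cur <- substr(b, pos, pos)
      mut <- b
      substr(mut, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      keys <- c(keys, mut)
      # sometimes tie the mutant's count with an existing key's
      counts <- c(counts, sample(c(sample(1:60, 1), counts[1]), 1))
    }
  }
  keep <- !duplicated(keys)
  tibble::tibble(key = keys[keep], count = as.integer(counts[keep]))
}

# Quadratic all-pairs implementation of the clustering parent rule:
# process keys in descending count (ties lexicographic), parent = the
# Hamming-1 key with strictly greater count (max count, then lexicographic
# smallest); roots found by following parent pointers.
cluster_oracle <- function(tbl) {
  tbl <- tbl[order(-tbl$count, tbl$key), ]
  keys <- tbl$key
  counts <- tbl$count
  n <- length(keys)
  mat <- do.call(rbind, strsplit(keys, "", fixed = TRUE))
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    d <- colSums(t(mat) != mat[i, ])
    cand <- which(d == 1L & counts > counts[i])
    if (length(cand) > 0) {
      parent[i] <- cand[order(-counts[cand], keys[cand])][1]
    }
  }
  root <- vapply(seq_len(n), function(i) {
    while (!is.na(parent[i])) i <- parent[i]
    i
  }, integer(1))
  tibble::tibble(
    key = keys, count = counts,
    parent_key = ifelse(is.na(parent), NA_character_, keys[parent]),
    root_key = keys[root]
  )
}

# Position-by-position IUPAC matcher (0-based offsets), with its own code
# table.
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

iupac_oracle <- function(pattern, sequence) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sc <- strsplit(sequence, "", fixed = TRUE)[[1]]
  lp <- length(pc)
  ls <- length(sc)
  if (lp > ls) return(integer())
  hits <- integer()
  for (off in 0:(ls - lp)) {
    ok <- TRUE
    for (j in seq_len(lp)) {
      if (!(sc[off + j] %in% ORACLE_IUPAC[[pc[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# Build a kmer_table directly from named counts (for contract tests of
# enrichment_ratio that need exact hand-set counts).
manual_kmer_table <- function(counts, k, sample_id = "manual",
                              total = sum(counts)) {
  tbl <- tibble::tibble(kmer = names(counts), count = as.integer(counts))
  tbl <- tbl[order(-tbl$count, tbl$kmer), ]
  tibble::new_tibble(tbl, k = as.integer(k), total = as.integer(total),
                     sample_id = sample_id, weighted = FALSE,
                     class = "kmer_table")
}

# Small two-sample simulation (one unenriched reference, one enriched
# "ChIP" sample) used by several round-trip tests.
two_sample_config <- function(n_elements, depth, error_rate = 0, n_rate = 0,
                              planted = tibble::tibble(pattern = "TTGACC",
                                                       fold = 10),
                              seed = 1L) {
  sim_config(
    n_elements = n_elements,
    barcode_table = tibble::tibble(
      sample_id = c("REF", "CHIP"),
      barcode = c("AACG", "TTGC"),
      rounds = c(0L, 1L)
    ),
    error_rate = error_rate, n_rate = n_rate,
    planted_motifs = planted, depth = depth, seed = seed
  )
}
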