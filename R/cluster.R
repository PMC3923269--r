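# Frequency-guided Hamming-distance-1 clustering of non-redundant SynE
# keys. Sequencing errors scatter a truly abundant element into a halo of
# low-count single-mismatch variants; clustering reassigns each variant to
# a more abundant Hamming-1 neighbour, using frequencies only (no base
# qualities). Each cluster is a tree: child -> parent edges connect a key to
# its chosen strictly-more-abundant neighbour, the root (the cluster's
# maximum-count key) is the representative, and the cumulative frequency is
# the sum of member counts.
#
# Parent rule (deterministic): processing unique keys in descending count
# (ties broken lexicographically ascending), a key's parent is the
# Hamming-1 neighbour present in the table with strictly greater count,
# choosing the neighbour of maximal count and breaking ties by the
# lexicographically smallest key. Keys with no such neighbour are roots.
# Equal-count neighbours never merge.

#' All Hamming-distance-1 neighbours of a 24-nt key
#'
#' @param key A single 24-nt ACGT string.
#' @return Character vector of the 72 sequences differing from `key` at
#'   exactly one position (24 positions x 3 alternative bases); `key`
#'   itself is excluded.
#' @examples
#' length(hamming_neighbors(strrep("A", 24)))  # 72
#' @export
hamming_neighbors <- function(key) {
  if (length(key) != 1L || !grepl("^[ACGT]{24}$", key)) {
    stop("`key` must be a single 24-nt ACGT string", call. = FALSE)
  }
  neighbor_matrix(key)[, 1]
}

# All Hamming-1 variants for a vector of equal-length keys: returns a
# (3*width) x n character matrix, column i holding the variants of keys[i].
# Builds all width x 4 single-base substitutions and drops, per key, the
# `width` no-op variants equal to the key itself.
neighbor_matrix <- function(keys, width = 24L) {
  bases <- c("A", "C", "G", "T")
  n <- length(keys)
  if (n == 0L) return(matrix(character(), nrow = 3L * width, ncol = 0L))
  rows <- vector("list", 4L * width)
  r <- 0L
  for (pos in seq_len(width)) {
    for (b in bases) {
      variant <- keys
      substr(variant, pos, pos) <- b
      r <- r + 1L
      rows[[r]] <- variant
    }
  }
  m <- matrix(unlist(rows), nrow = 4L * width, byrow = TRUE)
  keep <- m != matrix(keys, nrow = 4L * width, ncol = n, byrow = TRUE)
  matrix(m[keep], nrow = 3L * width)
}

#' Cluster a counted sample by frequency-guided Hamming-1 merging
#'
#' Implements the deterministic parent rule described above. The result is
#' a `syne_clusters` tibble with one row per input key (`key`, `count`,
#' `parent_key`, `root_key`), carrying `sample_id`, `n_unique_input`,
#' `n_clusters` and `n_filtered` as attributes. The output is independent
#' of input row order.
#'
#' @param counted A `counted_sample` (or tibble with `key`, `count`).
#' @return A `syne_clusters` object.
#' @export
build_clusters <- function(counted) {
  sample_id <- attr(counted, "sample_id") %||% NA_character_
  tbl <- tibble::as_tibble(counted)[c("key", "count")]
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$count), .data$key)
  n <- nrow(tbl)
  if (n == 0L) {
    out <- tibble::tibble(key = character(), count = integer(),
                          parent_key = character(), root_key = character())
    return(new_syne_clusters(out, sample_id, n_filtered = 0L))
  }
  if (anyDuplicated(tbl$key)) {
    stop("input keys must be unique (a non-redundant table)", call. = FALSE)
  }

  keys <- tbl$key
  counts <- tbl$count
  # candidate parent per key: enumerate the 72 variants, keep those present
  # with strictly greater count, pick max count then lexicographically
  # smallest key
  nb <- neighbor_matrix(keys)                       # 72 x n
  hit <- match(nb, keys)                            # index into keys, or NA
  cand_key_idx <- rep(seq_len(n), each = 72L)[!is.na(hit)]
  cand_parent <- hit[!is.na(hit)]
  keep <- counts[cand_parent] > counts[cand_key_idx]
  cand_key_idx <- cand_key_idx[keep]
  cand_parent <- cand_parent[keep]

  parent <- rep(NA_integer_, n)
  if (length(cand_key_idx) > 0) {
    best <- tibble::tibble(child = cand_key_idx, parent = cand_parent,
                           pc = counts[cand_parent], pk = keys[cand_parent]) |>
      dplyr::arrange(.data$child, dplyr::desc(.data$pc), .data$pk) |>
      dplyr::distinct(.data$child, .keep_all = TRUE)
    parent[best$child] <- best$parent
  }

  # resolve roots: a parent always has strictly greater count, hence a
  # smaller index in the count-descending order, so one forward pass works
  root <- seq_len(n)
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) root[i] <- root[parent[i]]
  }

  out <- tibble::tibble(
    key = keys, count = counts,
    parent_key = ifelse(is.na(parent), NA_character_, keys[parent]),
    root_key = keys[root]
  )
  new_syne_clusters(out, sample_id, n_filtered = sum(counts))
}

new_syne_clusters <- function(tbl, sample_id, n_filtered) {
  tibble::new_tibble(
    tbl,
    sample_id = sample_id,
    n_unique_input = nrow(tbl),
    n_clusters = length(unique(tbl$root_key)),
    n_filtered = as.integer(n_filtered),
    class = "syne_clusters"
  )
}

#' @export
print.syne_clusters <- function(x, ...) {
  cat(sprintf(
    "<syne_clusters> sample %s: %d unique keys in %d clusters (%.1f%% clustered)\n",
    attr(x, "sample_id"), attr(x, "n_unique_input"), attr(x, "n_clusters"),
    if (attr(x, "n_unique_input") > 0) pct_clustered(x) else 0))
  NextMethod()
}

#' @export
tidy.syne_clusters <- function(x, ...) as_bare_tibble(x)

#' One-row summary of a cluster set
#'
#' @param x A `syne_clusters` object.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `n_unique_input`, `n_clusters`,
#'   `pct_clustered`, `n_filtered`.
#' @export
glance.syne_clusters <- function(x, ...) {
  tibble::tibble(
    sample_id = attr(x, "sample_id"),
    n_unique_input = attr(x, "n_unique_input"),
    n_clusters = attr(x, "n_clusters"),
    pct_clustered = pct_clustered(x),
    n_filtered = attr(x, "n_filtered")
  )
}

#' Per-cluster table
#'
#' @param clusters A `syne_clusters` object.
#' @return Tibble with one row per cluster: `root_key`, `n_members`,
#'   `cumulative` (sum of member counts), sorted by cumulative descending
#'   then root key.
#' @export
cluster_table <- function(clusters) {
  tibble::as_tibble(clusters) |>
    dplyr::group_by(.data$root_key) |>
    dplyr::summarise(n_members = dplyr::n(),
                     cumulative = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$cumulative), .data$root_key)
}

#' Percentage of clustered sequences
#'
#' `100 * (n_unique - n_clusters) / n_unique`, rounded half-up to one
#' decimal: the fraction of unique sequences absorbed into a larger
#' cluster. Near 0 for a random library; high values indicate enrichment
#' of similar sequences.
#'
#' @param x A `syne_clusters` object, or the number of unique input keys.
#' @param ... Passed to methods.
#' @return A single number (one decimal place).
#' @examples
#' pct_clustered(82834, n_clusters = 44055)  # 46.8
#' @export
pct_clustered <- function(x, ...) UseMethod("pct_clustered")

#' @export
pct_clustered.syne_clusters <- function(x, ...) {
  pct_clustered.numeric(attr(x, "n_unique_input"),
                        n_clusters = attr(x, "n_clusters"))
}

#' @rdname pct_clustered
#' @param n_clusters Number of clusters formed.
#' @export
pct_clustered.numeric <- function(x, n_clusters, ...) {
  if (x <= 0) stop("% clustered is undefined for empty input", call. = FALSE)
  round_half_up(100 * (x - n_clusters) / x, 1)
}

#' Ranked cluster representatives
#'
#' @param clusters A `syne_clusters` object.
#' @param top_n Number of representatives to return; 0 returns all.
#' @return Tibble `root_key`, `cumulative`, sorted by cumulative descending,
#'   ties broken lexicographically, truncated to `top_n`.
#' @export
representatives <- function(clusters, top_n = 0L) {
  if (top_n < 0) stop("`top_n` must be >= 0", call. = FALSE)
  out <- cluster_table(clusters)[c("root_key", "cumulative")]
  if (top_n > 0L) out <- utils::head(out, top_n)
  out
}

#' Venn partition of cluster representatives across samples
#'
#' Compares representative keys (exact 24-nt identity) across two or more
#' cluster sets and counts, for every non-empty sample subset, the keys
#' whose representatives occur in exactly that subset. Partition counts sum
#' to the size of the union.
#'
#' @param cluster_sets Named list of >= 2 `syne_clusters` objects (names
#'   default to their `sample_id` attributes).
#' @return Tibble with `samples` (subset label, `&`-joined), `n_samples`,
#'   `n_keys`, and `keys` (list column of the shared keys).
#' @export
common_representatives <- function(cluster_sets) {
  if (length(cluster_sets) < 2L) {
    stop("need at least two cluster sets to compare", call. = FALSE)
  }
  ids <- names(cluster_sets) %||%
    purrr::map_chr(cluster_sets, ~ attr(.x, "sample_id"))
  if (is.null(names(cluster_sets))) names(cluster_sets) <- ids
  reps <- purrr::map(cluster_sets, ~ unique(.x$root_key[is.na(.x$parent_key)]))
  all_keys <- sort(unique(unlist(reps)))
  membership <- vapply(reps, function(r) all_keys %in% r,
                       logical(length(all_keys)))
  if (length(all_keys) == 1L) membership <- matrix(membership, nrow = 1L)
  label <- apply(membership, 1, function(m) paste(ids[m], collapse = "&"))
  split_keys <- split(all_keys, label)
  tibble::tibble(
    samples = names(split_keys),
    n_samples = unname(lengths(strsplit(names(split_keys), "&", fixed = TRUE))),
    n_keys = unname(lengths(split_keys)),
    keys = unname(split_keys)
  ) |>
    dplyr::arrange(dplyr::desc(.data$n_samples), .data$samples)
}
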