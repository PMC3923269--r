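# k-mer (5-7 nt) enrichment analysis: occurrence counts of every length-k
# window within the two variable 12-nt cores, and frequency ratios of a
# ChIP sample against the source sub-library it originated from. A k-mer
# with a high ratio is overrepresented among selected elements and is a
# candidate functional motif. Windows never span a core boundary: the
# flanks and spacer are constant in every element, so including them would
# flood the ranking with fixed-sequence k-mers (an `include_flanks` switch
# exposes the alternative).

#' Count k-mers over the variable cores of a sample
#'
#' Counts every length-k window within each 12-nt core separately
#' (2 x (13 - k) windows per element). By default each unique sequence
#' contributes once (counting over the non-redundant set); `weighted = TRUE`
#' multiplies each sequence's windows by its read count.
#'
#' @param counted A `counted_sample` (columns `left_core`, `right_core`,
#'   `count`).
#' @param k Window length, 1-12 (the analysis uses 5-7).
#' @param weighted Count each unique sequence once (`FALSE`, default) or by
#'   its read count (`TRUE`).
#' @param include_flanks Also count windows within the full 18-nt arms
#'   (flanks included). Default `FALSE`.
#' @return A `kmer_table`: tibble `kmer`, `count` (sorted by count
#'   descending then kmer), with attributes `k`, `total`, `sample_id`,
#'   `weighted`.
#' @export
count_kmers <- function(counted, k, weighted = FALSE, include_flanks = FALSE) {
  if (length(k) != 1L || is.na(k) || k < 1L || k > 12L) {
    stop("`k` must be a single integer in [1, 12]", call. = FALSE)
  }
  k <- as.integer(k)
  tbl <- tibble::as_tibble(counted)
  units <- if (include_flanks) {
    c(paste0("TCC", tbl$left_core, "GAA"), paste0("ATG", tbl$right_core, "ACT"))
  } else {
    c(tbl$left_core, tbl$right_core)
  }
  w <- if (weighted) rep(tbl$count, 2L) else rep(1L, 2L * nrow(tbl))
  width <- if (include_flanks) 18L else 12L
  n_win <- width - k + 1L
  if (length(units) == 0L || n_win < 1L) {
    out <- tibble::tibble(kmer = character(), count = integer())
  } else {
    kmers <- unlist(lapply(seq_len(n_win), function(j) {
      substr(units, j, j + k - 1L)
    }), use.names = FALSE)
    out <- tibble::tibble(kmer = kmers, w = rep(w, times = n_win)) |>
      dplyr::count(.data$kmer, wt = .data$w, name = "count") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$kmer)
    out$count <- as.integer(out$count)
  }
  tibble::new_tibble(
    out,
    k = k,
    total = sum(out$count),
    sample_id = attr(counted, "sample_id") %||% NA_character_,
    weighted = weighted,
    class = "kmer_table"
  )
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> sample %s, k = %d, total %d window(s)%s\n",
              attr(x, "sample_id"), attr(x, "k"), attr(x, "total"),
              if (attr(x, "weighted")) " (count-weighted)" else ""))
  NextMethod()
}

#' k-mer enrichment ratios of a sample against its source library
#'
#' For each k-mer m the relative frequency in a table is
#' `f(m) = (count(m) + a) / (total + a * 4^k)` with pseudocount `a`; the
#' enrichment ratio is `f_sample(m) / f_reference(m)`. Rows are ranked by
#' ratio descending, ties by sample count descending then k-mer. k-mers
#' observed in neither table are omitted (their ratio is exactly 1 at any
#' pseudocount). At `pseudocount = 0`, k-mers absent from the reference but
#' present in the sample have no finite ratio and are returned separately
#' in the `"reference_absent"` attribute.
#'
#' @param sample_table,reference_table `kmer_table`s of the same `k`
#'   (typically a ChIP sample and the sub-library it originated from).
#' @param pseudocount Non-negative pseudocount `a` (default 1; use 0 for
#'   exact ratios).
#' @return A `syne_enrichment` tibble: `kmer`, `count_sample`,
#'   `count_reference`, `ratio`; attributes `k`, `pseudocount`,
#'   `sample_id`, `reference_id`, `reference_absent`.
#' @export
enrichment_ratio <- function(sample_table, reference_table, pseudocount = 1) {
  k <- attr(sample_table, "k")
  if (!identical(k, attr(reference_table, "k"))) {
    stop("sample and reference k-mer tables have different k", call. = FALSE)
  }
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  a <- pseudocount
  tot_s <- attr(sample_table, "total")
  tot_r <- attr(reference_table, "total")
  merged <- dplyr::full_join(
    as_bare_tibble(sample_table),
    as_bare_tibble(reference_table),
    by = "kmer", suffix = c("_sample", "_reference")
  ) |>
    dplyr::mutate(
      count_sample = dplyr::coalesce(.data$count_sample, 0L),
      count_reference = dplyr::coalesce(.data$count_reference, 0L)
    )
  denom_s <- tot_s + a * 4^k
  denom_r <- tot_r + a * 4^k
  merged$ratio <- ((merged$count_sample + a) / denom_s) /
    ((merged$count_reference + a) / denom_r)
  absent <- a == 0 & merged$count_reference == 0L
  ref_absent <- merged[absent, c("kmer", "count_sample", "count_reference")]
  out <- merged[!absent, ] |>
    dplyr::arrange(dplyr::desc(.data$ratio), dplyr::desc(.data$count_sample),
                   .data$kmer)
  tibble::new_tibble(
    out,
    k = k,
    pseudocount = a,
    sample_id = attr(sample_table, "sample_id"),
    reference_id = attr(reference_table, "sample_id"),
    reference_absent = tibble::as_tibble(ref_absent),
    class = "syne_enrichment"
  )
}

#' @export
print.syne_enrichment <- function(x, ...) {
  cat(sprintf(
    "<syne_enrichment> %s vs %s, k = %d, pseudocount %g (%d reference-absent)\n",
    attr(x, "sample_id"), attr(x, "reference_id"), attr(x, "k"),
    attr(x, "pseudocount"), nrow(attr(x, "reference_absent"))))
  NextMethod()
}

#' @export
tidy.syne_enrichment <- function(x, ...) as_bare_tibble(x)

#' @export
glance.syne_enrichment <- function(x, ...) {
  tibble::tibble(
    sample_id = attr(x, "sample_id"),
    reference_id = attr(x, "reference_id"),
    k = attr(x, "k"),
    pseudocount = attr(x, "pseudocount"),
    n_kmers = nrow(x),
    n_reference_absent = nrow(attr(x, "reference_absent")),
    top_kmer = if (nrow(x) > 0) x$kmer[1] else NA_character_,
    top_ratio = if (nrow(x) > 0) x$ratio[1] else NA_real_
  )
}

#' Coupled partner cores of an anchor core
#'
#' For an anchor 12-nt core on one side of the element, returns every core
#' observed on the other side together with its summed read count — the
#' raw material for asking which partners a functional core recruits.
#'
#' @param counted A `counted_sample`.
#' @param anchor_core A 12-nt ACGT string.
#' @param side `"left"` if the anchor is a left core (partners are right
#'   cores), `"right"` for the converse.
#' @return Tibble `partner_core`, `count`, sorted by count descending then
#'   partner; attributes `anchor` and `side`.
#' @export
coupled_partners <- function(counted, anchor_core, side = c("left", "right")) {
  side <- match.arg(side)
  if (length(anchor_core) != 1L || !grepl("^[ACGT]{12}$", anchor_core)) {
    stop("`anchor_core` must be a single 12-nt ACGT string", call. = FALSE)
  }
  tbl <- tibble::as_tibble(counted)
  if (side == "left") {
    hits <- tbl[tbl$left_core == anchor_core, c("right_core", "count")]
    names(hits)[1] <- "partner_core"
  } else {
    hits <- tbl[tbl$right_core == anchor_core, c("left_core", "count")]
    names(hits)[1] <- "partner_core"
  }
  out <- hits |>
    dplyr::count(.data$partner_core, wt = .data$count, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$partner_core)
  out$count <- as.integer(out$count)
  attr(out, "anchor") <- anchor_core
  attr(out, "side") <- side
  out
}

#' Export coupled partner cores as MEME-ready FASTA
#'
#' One record per partner core (12-nt sequence); the header carries the
#' anchor, side, rank and count (`>anchor|side|rank|count`). The file is a
#' direct input for external motif discovery (e.g. `meme -dna`).
#'
#' @param partner_lists Output of [coupled_partners()], or a (possibly
#'   named) list of such tibbles for several anchors.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
export_meme_fasta <- function(partner_lists, path) {
  if (is.data.frame(partner_lists)) partner_lists <- list(partner_lists)
  total <- sum(purrr::map_int(partner_lists, nrow))
  if (total == 0L) {
    stop("no partner cores to export", call. = FALSE)
  }
  headers <- unlist(purrr::map(partner_lists, function(p) {
    sprintf("%s|%s|%d|%d", attr(p, "anchor") %||% "anchor",
            attr(p, "side") %||% "side", seq_len(nrow(p)), p$count)
  }), use.names = FALSE)
  out <- Biostrings::DNAStringSet(
    unlist(purrr::map(partner_lists, "partner_core"), use.names = FALSE))
  names(out) <- headers
  Biostrings::writeXStringSet(out, path, format = "fasta")
  invisible(path)
}
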