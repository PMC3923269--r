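# Pre-processing: demultiplexing, mate joining, positional core extraction,
# and non-redundant count tables.
#
# Extraction follows the positional design of the construct: after barcode
# trimming, the last 18 nt of the forward mate span the left arm
# (TCC + 12-nt core + GAA) and the first 18 nt of the reverse-complemented
# reverse mate span the right arm (ATG + 12-nt core + ACT). The flanks are
# required at fixed positions — no shifting — and any ambiguous base (N)
# inside a core rejects the pair.

#' Demultiplex read pairs by exact barcode match
#'
#' A pair is assigned to a sample iff the first `barcode_len` bases of its
#' forward mate exactly equal that sample's barcode (no mismatch rescue).
#' The barcode is trimmed from both mates of assigned pairs. Unassigned
#' pairs are counted (attribute `n_unassigned`) and dropped.
#'
#' @param pairs Tibble with columns `read_id`, `fwd_seq`, `rev_seq`.
#' @param barcode_table Tibble with columns `sample_id`, `barcode`
#'   (same-length, pairwise-distinct).
#' @param barcode_len Barcode length; defaults to the table's barcode width.
#' @return The assigned pairs with a `sample_id` column and trimmed mates;
#'   attribute `n_unassigned` carries the number of unassigned pairs.
#' @export
demultiplex <- function(pairs, barcode_table, barcode_len = NULL) {
  barcode_table <- tibble::as_tibble(barcode_table)
  if (nrow(barcode_table) == 0) {
    stop("barcode table is empty", call. = FALSE)
  }
  widths <- unique(nchar(barcode_table$barcode))
  if (length(widths) != 1L) {
    stop("all barcodes must have the same length", call. = FALSE)
  }
  if (anyDuplicated(barcode_table$barcode)) {
    stop("duplicate barcodes in barcode table", call. = FALSE)
  }
  bl <- barcode_len %||% widths
  if (bl != widths) {
    stop("`barcode_len` does not match the barcode table", call. = FALSE)
  }
  prefix <- substr(pairs$fwd_seq, 1L, bl)
  idx <- match(prefix, barcode_table$barcode)
  assigned <- !is.na(idx)
  out <- tibble::tibble(
    read_id = pairs$read_id[assigned],
    sample_id = barcode_table$sample_id[idx[assigned]],
    fwd_seq = substr(pairs$fwd_seq[assigned], bl + 1L, nchar(pairs$fwd_seq[assigned])),
    rev_seq = substr(pairs$rev_seq[assigned], bl + 1L, nchar(pairs$rev_seq[assigned]))
  )
  n_un <- sum(!assigned)
  if (n_un > 0) {
    message(sprintf("demultiplex: %d pair(s) unassigned (no exact barcode match)",
                    n_un))
  }
  attr(out, "n_unassigned") <- n_un
  out
}

#' Join mates into one plus-strand sequence
#'
#' Returns `fwd_seq` concatenated with the reverse complement of `rev_seq`
#' (N reverse-complements to N), the orientation in which both arm windows
#' read on the plus strand.
#'
#' @param fwd_seq,rev_seq Character vectors over `{A,C,G,T,N}`.
#' @return Character vector of joined sequences.
#' @examples
#' join_mates("ACGT", "AAAA")  # "ACGTTTTT"
#' @export
join_mates <- function(fwd_seq, rev_seq) {
  assert_nucleotides(fwd_seq, allow_n = TRUE)
  assert_nucleotides(rev_seq, allow_n = TRUE)
  paste0(fwd_seq, revcomp(rev_seq))
}

#' Extract SynE cores from trimmed mate pairs
#'
#' Applies the positional + pattern rule: the left window is the last 18 nt
#' of the (barcode-trimmed) forward mate and must match
#' `TCC[ACGT]{12}GAA`; the right window is the first 18 nt of the
#' reverse-complemented reverse mate and must match `ATG[ACGT]{12}ACT`.
#' Rejections are classified, checked in this order: `too_short`,
#' `flank_left`, `flank_right`, `ambiguous_base` (an N in a flank reports
#' as a flank failure; an N in a core as `ambiguous_base`).
#'
#' @param pairs Tibble with columns `fwd_seq`, `rev_seq` (barcode already
#'   trimmed); other columns are carried through.
#' @return `pairs` plus columns `left_core`, `right_core`, `key` (24-nt
#'   concatenation; NA where rejected) and `reason` (NA where accepted).
#' @export
extract_synes <- function(pairs) {
  fwd <- pairs$fwd_seq
  rev <- pairs$rev_seq
  assert_nucleotides(fwd, allow_n = TRUE)
  assert_nucleotides(rev, allow_n = TRUE)
  n <- length(fwd)
  reason <- rep(NA_character_, n)
  lcore <- rep(NA_character_, n)
  rcore <- rep(NA_character_, n)

  short <- nchar(fwd) < 18L | nchar(rev) < 18L
  ok <- !short
  lw <- rep(NA_character_, n)
  rw <- rep(NA_character_, n)
  if (any(ok)) {
    lw[ok] <- substr(fwd[ok], nchar(fwd[ok]) - 17L, nchar(fwd[ok]))
    rc <- revcomp(rev[ok])
    rw[ok] <- substr(rc, 1L, 18L)
  }
  flank_l <- ok & !(substr(lw, 1L, 3L) == "TCC" & substr(lw, 16L, 18L) == "GAA")
  flank_r <- ok & !flank_l &
    !(substr(rw, 1L, 3L) == "ATG" & substr(rw, 16L, 18L) == "ACT")
  cand <- ok & !flank_l & !flank_r
  lc <- substr(lw, 4L, 15L)
  rc2 <- substr(rw, 4L, 15L)
  ambig <- cand & (grepl("[^ACGT]", lc) | grepl("[^ACGT]", rc2))
  accept <- cand & !ambig

  reason[short] <- "too_short"
  reason[flank_l] <- "flank_left"
  reason[flank_r] <- "flank_right"
  reason[ambig] <- "ambiguous_base"
  lcore[accept] <- lc[accept]
  rcore[accept] <- rc2[accept]

  out <- tibble::as_tibble(pairs)
  out$left_core <- lcore
  out$right_core <- rcore
  out$key <- ifelse(accept, paste0(lcore, rcore), NA_character_)
  out$reason <- reason
  out
}

#' Summarise rejection reasons
#'
#' @param extracted Output of [extract_synes()].
#' @return Tibble with columns `reason` (including `"accepted"`) and `n`;
#'   the counts sum to `nrow(extracted)`.
#' @export
rejection_summary <- function(extracted) {
  r <- dplyr::coalesce(extracted$reason, "accepted")
  lev <- c("accepted", "too_short", "flank_left", "flank_right", "ambiguous_base")
  tibble::tibble(reason = lev,
                 n = as.integer(table(factor(r, levels = lev))))
}

#' Build a non-redundant count table for one sample
#'
#' Tallies accepted SynEs by their 24-nt key. The result is a
#' `counted_sample`: a tibble (`key`, `left_core`, `right_core`, `count`,
#' sorted by count descending then key) carrying the sample's bookkeeping
#' as attributes (`sample_id`, `n_raw` assigned reads, `n_filtered`
#' extracted SynEs, `n_unique` distinct keys).
#'
#' @param extracted Output of [extract_synes()] (rejected rows are ignored),
#'   or any tibble with a `key` column of 24-nt ACGT strings.
#' @param sample_id Sample label.
#' @param n_raw Total reads assigned to the sample (>= number accepted);
#'   defaults to `nrow(extracted)`.
#' @return A `counted_sample` tibble.
#' @export
tally_synes <- function(extracted, sample_id, n_raw = nrow(extracted)) {
  keys <- extracted$key
  if (!is.null(extracted$reason)) keys <- keys[is.na(extracted$reason)]
  keys <- keys[!is.na(keys)]
  if (!all(grepl("^[ACGT]{24}$", keys))) {
    stop("all SynE keys must be 24-nt ACGT strings", call. = FALSE)
  }
  n_filtered <- length(keys)
  if (n_raw < n_filtered) {
    stop("`n_raw` cannot be smaller than the number of extracted SynEs",
         call. = FALSE)
  }
  counts <- tibble::tibble(key = keys) |>
    dplyr::count(.data$key, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$key) |>
    dplyr::mutate(
      left_core = substr(.data$key, 1L, 12L),
      right_core = substr(.data$key, 13L, 24L),
      .after = "key"
    )
  new_counted_sample(counts, sample_id = sample_id, n_raw = as.integer(n_raw))
}

new_counted_sample <- function(counts, sample_id, n_raw) {
  out <- tibble::new_tibble(
    counts,
    sample_id = sample_id,
    n_raw = n_raw,
    n_filtered = as.integer(sum(counts$count)),
    n_unique = nrow(counts),
    class = "counted_sample"
  )
  out
}

#' @export
print.counted_sample <- function(x, ...) {
  cat(sprintf(
    "<counted_sample> sample %s: %d raw, %d extracted, %d unique\n",
    attr(x, "sample_id"), attr(x, "n_raw"), attr(x, "n_filtered"),
    attr(x, "n_unique")))
  NextMethod()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.counted_sample <- function(x, ...) {
  as_bare_tibble(x)
}

#' One-row summary of a counted sample
#'
#' @param x A `counted_sample`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `n_raw`, `n_filtered`, `n_unique`,
#'   `pct_unique`.
#' @export
glance.counted_sample <- function(x, ...) {
  tibble::tibble(
    sample_id = attr(x, "sample_id"),
    n_raw = attr(x, "n_raw"),
    n_filtered = attr(x, "n_filtered"),
    n_unique = attr(x, "n_unique"),
    pct_unique = pct_unique(x)
  )
}

#' Percentage of unique sequences
#'
#' `100 * n_unique / n_filtered`, rounded half-up to one decimal — the
#' "% unique sequences" complexity statistic. Values above ~90% indicate an
#' essentially random library; a sharp drop indicates selection.
#'
#' @param x A `counted_sample`, or the number of unique sequences.
#' @param ... Passed to methods.
#' @return A single number (one decimal place).
#' @examples
#' pct_unique(234498, n_filtered = 259149)  # 90.5
#' @export
pct_unique <- function(x, ...) UseMethod("pct_unique")

#' @export
pct_unique.counted_sample <- function(x, ...) {
  pct_unique.numeric(attr(x, "n_unique"), n_filtered = attr(x, "n_filtered"))
}

#' @rdname pct_unique
#' @param n_filtered Total extracted sequences (> 0).
#' @export
pct_unique.numeric <- function(x, n_filtered, ...) {
  if (n_filtered <= 0) {
    stop("% unique is undefined for n_filtered = 0", call. = FALSE)
  }
  round_half_up(100 * x / n_filtered, 1)
}

#' Write / read a non-redundant count table
#'
#' Plain TSV with columns `key`, `left_core`, `right_core`, `count`.
#'
#' @param counted A `counted_sample`.
#' @param path File path.
#' @return `write_counts()`: the path, invisibly. `read_counts()`: a
#'   `counted_sample` (with `n_raw` as supplied, defaulting to the count
#'   total).
#' @export
write_counts <- function(counted, path) {
  readr::write_tsv(tibble::as_tibble(counted), path)
  invisible(path)
}

#' @rdname write_counts
#' @param sample_id Sample label for the re-read table.
#' @param n_raw Raw assigned-read total, if known.
#' @export
read_counts <- function(path, sample_id, n_raw = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    key = "c", left_core = "c", right_core = "c", count = "i"))
  new_counted_sample(tbl, sample_id = sample_id,
                     n_raw = as.integer(n_raw %||% sum(tbl$count)))
}
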