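# Known-motif annotation: a PLACE-style table of named IUPAC patterns is
# scanned against the two 18-nt arms of each SynE (flanks included by
# default, since the real construct contains them; a cores-only mode is
# available). Arms are scanned independently and never concatenated — a
# constant 20-bp spacer separates them in the construct, so a match
# spanning the junction would be an artefact.

#' Load a PLACE-style IUPAC motif table
#'
#' Reads a two-column TSV (`name<TAB>pattern`, no header) of named IUPAC
#' motifs and applies the database filter: patterns longer than 14 nt are
#' dropped and exact-duplicate patterns are collapsed (first name kept);
#' order is otherwise preserved. A three-motif demo table (W-box TTGACY,
#' GCC-box GCCGCC, as-1 TGACG) ships with the package; full PLACE flat
#' files are not redistributed — convert them to this two-column layout to
#' use them.
#'
#' @param path TSV path; defaults to the bundled demo table.
#' @param max_len Maximum retained pattern length (default 14).
#' @return Tibble with columns `motif`, `pattern`.
#' @examples
#' read_motif_db()
#' @export
read_motif_db <- function(path = demo_motif_db(), max_len = 14L) {
  tbl <- readr::read_tsv(path, col_names = c("motif", "pattern"),
                         col_types = "cc", comment = "#")
  for (i in seq_len(nrow(tbl))) {
    ok <- tryCatch({ assert_iupac(tbl$pattern[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      stop(sprintf("invalid IUPAC pattern on line %d of %s: \"%s\"",
                   i, path, tbl$pattern[i]), call. = FALSE)
    }
  }
  tbl <- tbl[nchar(tbl$pattern) <= max_len, ]
  tbl <- tbl[!duplicated(tbl$pattern), ]
  tibble::as_tibble(tbl)
}

#' Path to the bundled demo motif table
#' @return File path of the three-motif demo TSV.
#' @export
demo_motif_db <- function() {
  system.file("extdata", "demo_motifs.tsv", package = "synescreen",
              mustWork = TRUE)
}

#' Match an IUPAC pattern against sequences
#'
#' Reports every 0-based offset at which each position of the pattern's
#' IUPAC class contains the sequence base; overlapping matches are all
#' reported. A pattern longer than the sequence yields no match (not an
#' error).
#'
#' @param pattern A single IUPAC string.
#' @param sequence Character vector of ACGT sequences.
#' @return For a single sequence, an integer vector of 0-based offsets;
#'   for several, a list of such vectors.
#' @examples
#' iupac_match("TGACG", "ATGACGT")  # 1
#' iupac_match("TTGACY", "TTGACT")  # 0
#' @export
iupac_match <- function(pattern, sequence) {
  assert_iupac(pattern)
  assert_nucleotides(sequence, arg = "sequence")
  # lookahead makes overlapping occurrences visible to gregexpr
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  hits <- gregexpr(rx, sequence, perl = TRUE)
  out <- lapply(hits, function(h) {
    if (h[1] == -1L) integer() else as.integer(h) - 1L
  })
  if (length(sequence) == 1L) out[[1]] else out
}

#' Scan SynE arms for known motifs
#'
#' Scans the two arms of every unique SynE in a sample against a motif
#' table. By default the full 18-nt arms (`TCC` + core + `GAA`,
#' `ATG` + core + `ACT`) are scanned on both strands; minus-strand hits
#' are found by matching the reverse-complemented pattern and are reported
#' at the plus-strand coordinate of their leftmost matched base.
#'
#' @param counted A `counted_sample` (or tibble with `left_core`,
#'   `right_core`).
#' @param motifs Motif tibble from [read_motif_db()].
#' @param both_strands Also scan the minus strand (default `TRUE`).
#' @param arms `"full"` (18-nt arms, flanks included; default) or
#'   `"core"` (bare 12-nt cores).
#' @return Tibble of hits: `key`, `arm` (`left`/`right`), `offset`
#'   (0-based within the scanned arm), `strand` (`+`/`-`), `motif`,
#'   `pattern`.
#' @export
scan_motifs <- function(counted, motifs, both_strands = TRUE,
                        arms = c("full", "core")) {
  arms <- match.arg(arms)
  tbl <- tibble::as_tibble(counted)
  key <- if ("key" %in% names(tbl)) tbl$key else
    paste0(tbl$left_core, tbl$right_core)
  arm_seqs <- list(
    left = if (arms == "full") paste0("TCC", tbl$left_core, "GAA") else tbl$left_core,
    right = if (arms == "full") paste0("ATG", tbl$right_core, "ACT") else tbl$right_core
  )
  res <- list()
  for (m in seq_len(nrow(motifs))) {
    pats <- tibble::tibble(pattern = motifs$pattern[m], strand = "+")
    if (both_strands) {
      pats <- dplyr::bind_rows(pats, tibble::tibble(
        pattern = iupac_revcomp(motifs$pattern[m]), strand = "-"))
    }
    for (p in seq_len(nrow(pats))) {
      for (arm in names(arm_seqs)) {
        seqs <- arm_seqs[[arm]]
        if (length(seqs) == 0 || nchar(pats$pattern[p]) > nchar(seqs[1])) next
        hits <- iupac_match(pats$pattern[p], seqs)
        if (length(seqs) == 1L) hits <- list(hits)
        n_hit <- lengths(hits)
        if (sum(n_hit) == 0) next
        res[[length(res) + 1L]] <- tibble::tibble(
          key = rep(key, n_hit),
          arm = arm,
          offset = unlist(hits),
          strand = pats$strand[p],
          motif = motifs$motif[m],
          pattern = motifs$pattern[m]
        )
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(key = character(), arm = character(),
                          offset = integer(), strand = character(),
                          motif = character(), pattern = character()))
  }
  dplyr::bind_rows(res) |>
    dplyr::arrange(.data$key, .data$arm, .data$offset, .data$strand,
                   .data$motif)
}

#' Annotate cluster representatives with known motifs
#'
#' Scans each representative SynE against the motif table and reports the
#' set of matched motif names; representatives matching nothing are
#' labelled `"novel"`.
#'
#' @param clusters A `syne_clusters` object.
#' @param motifs Motif tibble from [read_motif_db()].
#' @param ... Passed to [scan_motifs()] (e.g. `both_strands`, `arms`).
#' @return Tibble `root_key`, `annotation` (comma-joined motif names or
#'   `"novel"`), `n_motifs`.
#' @export
annotate_representatives <- function(clusters, motifs, ...) {
  reps <- representatives(clusters, top_n = 0L)
  rep_tbl <- tibble::tibble(
    key = reps$root_key,
    left_core = substr(reps$root_key, 1L, 12L),
    right_core = substr(reps$root_key, 13L, 24L)
  )
  hits <- scan_motifs(rep_tbl, motifs, ...)
  ann <- hits |>
    dplyr::distinct(.data$key, .data$motif) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(annotation = paste(sort(unique(.data$motif)),
                                        collapse = ","),
                     n_motifs = dplyr::n(), .groups = "drop")
  reps |>
    dplyr::transmute(root_key = .data$root_key) |>
    dplyr::left_join(ann, by = c(root_key = "key")) |>
    dplyr::mutate(
      annotation = dplyr::coalesce(.data$annotation, "novel"),
      n_motifs = dplyr::coalesce(.data$n_motifs, 0L)
    )
}
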