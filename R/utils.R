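# Shared low-level helpers: nucleotide alphabet checks, reverse
# complementation, IUPAC code handling, half-up rounding.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of nucleotide sequences
#'
#' Vectorised reverse complementation over the `{A,C,G,T,N}` alphabet
#' (N maps to N). Delegates to [Biostrings::reverseComplement()].
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAN"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  assert_nucleotides(x, allow_n = TRUE)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- NULL
  out
}

# Reverse complement of an IUPAC pattern (degenerate codes allowed).
iupac_revcomp <- function(pattern) {
  assert_iupac(pattern)
  chars <- rev(strsplit(pattern, "", fixed = TRUE)[[1]])
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

# Translate an IUPAC pattern into a plain character-class regex.
iupac_to_regex <- function(pattern) {
  assert_iupac(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  cls <- vapply(chars, function(ch) {
    bases <- IUPAC_CODES[[ch]]
    if (nchar(bases) == 1L) bases else paste0("[", bases, "]")
  }, character(1))
  paste(cls, collapse = "")
}

assert_nucleotides <- function(x, allow_n = FALSE, arg = deparse(substitute(x))) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !is.na(x) & !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf(
      "`%s` contains non-nucleotide characters (first offender: \"%s\")",
      arg, x[which(bad)[1]]
    ), call. = FALSE)
  }
  invisible(x)
}

assert_iupac <- function(pattern, arg = deparse(substitute(pattern))) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      nchar(pattern) < 1L) {
    stop(sprintf("`%s` must be a single non-empty IUPAC string", arg),
         call. = FALSE)
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop(sprintf("invalid IUPAC symbol(s) in `%s`: %s", arg,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(pattern)
}

#' Round half away from zero
#'
#' Fixed-decimal rounding with halves rounded up, as used for the percentage
#' statistics of the summary table (base `round()` rounds halves to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Internal: %||% without importing from rlang at top level everywhere.
`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: plain tibble, with result-class and bookkeeping attributes
# stripped.
as_bare_tibble <- function(x) {
  do.call(tibble::tibble, as.list(x))
}
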