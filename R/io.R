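# Paired-read file I/O. Sequence containers and parsing are delegated to
# Biostrings; the package-level representation of a read pair is a tibble
# row (read_id, fwd_seq, rev_seq).

#' Write paired reads to FASTQ/FASTA mate files
#'
#' Mate ids get `/1` and `/2` suffixes; FASTQ qualities are a constant `I`.
#'
#' @param reads Tibble with columns `read_id`, `fwd_seq`, `rev_seq`.
#' @param fwd_path,rev_path Output paths for the two mates.
#' @param format `"fastq"` or `"fasta"`.
#' @return Invisibly, `c(fwd_path, rev_path)`.
#' @export
write_read_pairs <- function(reads, fwd_path, rev_path,
                             format = c("fastq", "fasta")) {
  format <- match.arg(format)
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    if (format == "fastq") {
      q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
      Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    } else {
      Biostrings::writeXStringSet(x, path, format = "fasta")
    }
  }
  write_one(reads$fwd_seq, paste0(reads$read_id, "/1"), fwd_path)
  write_one(reads$rev_seq, paste0(reads$read_id, "/2"), rev_path)
  invisible(c(fwd_path, rev_path))
}

# Strip a trailing mate tag: anything after whitespace, then /1 or /2.
strip_mate_suffix <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

#' Read paired reads from FASTQ/FASTA mate files
#'
#' Mates are matched by their shared id after stripping a `/1`/`/2` or
#' space-delimited tag; an error is raised if the files do not pair up.
#'
#' @param fwd_path,rev_path Paths to the forward and reverse mate files.
#' @param format `"fastq"`, `"fasta"`, or `NULL` to infer from the file
#'   extension.
#' @return Tibble with columns `read_id`, `fwd_seq`, `rev_seq`.
#' @export
read_read_pairs <- function(fwd_path, rev_path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", fwd_path)) "fastq" else "fasta"
  }
  fwd <- Biostrings::readDNAStringSet(fwd_path, format = format)
  rev <- Biostrings::readDNAStringSet(rev_path, format = format)
  fid <- strip_mate_suffix(names(fwd))
  rid <- strip_mate_suffix(names(rev))
  m <- match(fid, rid)
  if (anyNA(m) || length(fid) != length(rid)) {
    stop("mate files do not pair up by read id", call. = FALSE)
  }
  tibble::tibble(
    read_id = fid,
    fwd_seq = unname(as.character(fwd)),
    rev_seq = unname(as.character(rev))[m]
  )
}
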