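# Truth-tracked simulator for sequential-enrichment SynE screens.
#
# A SynE library is a set of elements, each carrying two independent 12-nt
# random cores in fixed flanks (TCC...GAA on the left arm, ATG...ACT on the
# right arm). Enrichment rounds are modelled as weighted multinomial
# sampling: elements whose cores carry a planted motif are drawn with
# elevated probability, multiplicatively per round. Reads are 36-nt
# paired-end with a sample barcode at the 5' end of both mates, per-base
# substitution noise, and per-base N conversion; the pre-noise draw is
# recorded as a truth table so every downstream stage can be validated
# against known counts.

DEFAULT_BARCODES <- tibble::tibble(
  sample_id = paste0("S", 1:8),
  barcode   = c("AACG", "CCTA", "GGAT", "TTGC", "ACTC", "CAGA", "GTCT", "TGAG"),
  # number of enrichment rounds applied before sequencing: the main library
  # and the two sub-libraries are unenriched; three samples follow two ChIP
  # rounds and two samples a third round
  rounds    = c(0L, 0L, 0L, 2L, 2L, 3L, 3L, 2L)
)

#' Simulation configuration
#'
#' Collects the parameters of the screen simulator and checks their
#' invariants. Defaults are a desktop-scale rendition of the screened
#' libraries: a large random library sampled sparsely (library size well
#' above per-sample depth), 36-nt paired-end reads, 4-nt barcodes on both
#' mates, 1% per-base substitution error, and a canonical defense-responsive
#' W-box planted at 10-fold enrichment.
#'
#' @param n_elements Number of distinct library elements (default 200000).
#' @param barcode_table Tibble with columns `sample_id`, `barcode`, and
#'   optionally `rounds` (integer enrichment rounds per sample; default 0).
#'   Barcodes must be same-length, pairwise distinct ACGT strings.
#' @param read_length Read length in nt (default 36).
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param n_rate Per-base probability of emitting `N`.
#' @param planted_motifs Tibble with columns `pattern` (IUPAC) and `fold`
#'   (>= 1): elements whose cores match a pattern are sampled `fold` times
#'   more per enrichment round.
#' @param depth Reads per sample (default 50000).
#' @param filler Short sequence cycled to fill read positions outside the
#'   barcode and the 18-nt arm window; extraction never reads it.
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_elements = 100, depth = 50, seed = 1)
#' @export
sim_config <- function(n_elements = 200000L,
                       barcode_table = DEFAULT_BARCODES,
                       read_length = 36L,
                       error_rate = 0.01,
                       n_rate = 0.001,
                       planted_motifs = tibble::tibble(pattern = "TTGACY", fold = 10),
                       depth = 50000L,
                       filler = "ACGT",
                       seed = 1L) {
  if (length(n_elements) != 1L || is.na(n_elements) || n_elements < 0) {
    stop("`n_elements` must be a single non-negative integer", call. = FALSE)
  }
  if (error_rate < 0 || n_rate < 0 || error_rate + n_rate > 1) {
    stop("`error_rate` and `n_rate` must be non-negative with sum <= 1",
         call. = FALSE)
  }
  barcode_table <- tibble::as_tibble(barcode_table)
  if (nrow(barcode_table) == 0) stop("`barcode_table` is empty", call. = FALSE)
  if (!all(c("sample_id", "barcode") %in% names(barcode_table))) {
    stop("`barcode_table` needs columns sample_id and barcode", call. = FALSE)
  }
  if (!"rounds" %in% names(barcode_table)) barcode_table$rounds <- 0L
  assert_nucleotides(barcode_table$barcode, arg = "barcode")
  bl <- unique(nchar(barcode_table$barcode))
  if (length(bl) != 1L) stop("all barcodes must have the same length", call. = FALSE)
  if (anyDuplicated(barcode_table$barcode)) {
    stop("barcodes must be pairwise distinct", call. = FALSE)
  }
  planted_motifs <- tibble::as_tibble(planted_motifs)
  if (nrow(planted_motifs) > 0) {
    stopifnot(all(c("pattern", "fold") %in% names(planted_motifs)))
    purrr::walk(planted_motifs$pattern, assert_iupac, arg = "planted pattern")
    if (any(planted_motifs$fold < 1)) {
      stop("planted motif folds must be >= 1", call. = FALSE)
    }
  }
  if (read_length < bl + 18L) {
    stop(sprintf(
      "`read_length` (%d) too short: need barcode (%d) + 18-nt arm window",
      read_length, bl), call. = FALSE)
  }
  structure(list(
    n_elements = as.integer(n_elements),
    barcode_table = barcode_table,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    n_rate = n_rate,
    planted_motifs = planted_motifs,
    depth = as.integer(depth),
    filler = filler,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a random SynE library
#'
#' Each element carries two independent 12-nt cores drawn i.i.d. uniformly
#' over `{A,C,G,T}`; the element key is the 24-nt concatenation of left and
#' right core. Deterministic in `(n_elements, seed)`.
#'
#' @param n_elements Number of elements (>= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `key`, `left_core`, `right_core`.
#' @examples
#' make_library(3, seed = 7)
#' @export
make_library <- function(n_elements, seed = 1L) {
  if (length(n_elements) != 1L || is.na(n_elements) || n_elements < 0) {
    stop("`n_elements` must be a single non-negative integer", call. = FALSE)
  }
  n_elements <- as.integer(n_elements)
  empty <- tibble::tibble(key = character(), left_core = character(),
                          right_core = character())
  if (n_elements == 0L) return(empty)
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    draw <- function() {
      m <- matrix(sample(bases, n_elements * 12L, replace = TRUE), ncol = 12L)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    left <- draw()
    right <- draw()
    tibble::tibble(key = paste0(left, right), left_core = left,
                   right_core = right)
  })
}

#' Assign enrichment weights from planted motifs
#'
#' The sampling weight of an element is the product of the folds of every
#' planted motif whose IUPAC pattern matches either 12-nt core on the plus
#' strand; elements matching nothing get weight 1. One application models a
#' single selection round; sequential rounds raise the weight to the power
#' of the round count.
#'
#' @param library Tibble from [make_library()].
#' @param planted_motifs Tibble with columns `pattern`, `fold` (folds >= 1).
#' @return Tibble with columns `key`, `weight`.
#' @export
enrich_weights <- function(library, planted_motifs) {
  planted_motifs <- tibble::as_tibble(planted_motifs)
  w <- rep(1, nrow(library))
  if (nrow(planted_motifs) > 0) {
    if (any(planted_motifs$fold < 1)) {
      stop("planted motif folds must be >= 1", call. = FALSE)
    }
    for (i in seq_len(nrow(planted_motifs))) {
      rx <- iupac_to_regex(planted_motifs$pattern[i])
      hit <- grepl(rx, library$left_core) | grepl(rx, library$right_core)
      w[hit] <- w[hit] * planted_motifs$fold[i]
    }
  }
  tibble::tibble(key = library$key, weight = w)
}

# Cycle `filler` out to n characters.
fill_seq <- function(filler, n) {
  if (n <= 0) return("")
  substr(strrep(filler, ceiling(n / nchar(filler))), 1L, n)
}

# Per-base noise: each base is independently substituted (uniformly to one
# of the 3 alternative bases) with prob error_rate, or replaced by N with
# prob n_rate. Input sequences must be same-length and pure ACGT.
apply_noise <- function(seqs, error_rate, n_rate) {
  if (length(seqs) == 0 || (error_rate <= 0 && n_rate <= 0)) return(seqs)
  L <- nchar(seqs[[1]])
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                ncol = L, byrow = TRUE)
  u <- stats::runif(length(mat))
  sub_i <- which(u < error_rate)
  n_i <- which(u >= error_rate & u < error_rate + n_rate)
  if (length(sub_i) > 0) {
    bases <- c("A", "C", "G", "T")
    # row b of `alts`: the three bases other than bases[b]
    alts <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                  c("A", "C", "T"), c("A", "C", "G"))
    pick <- sample.int(3L, length(sub_i), replace = TRUE)
    mat[sub_i] <- alts[cbind(match(mat[sub_i], bases), pick)]
  }
  if (length(n_i) > 0) mat[n_i] <- "N"
  do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
}

#' Emit barcoded paired-end reads for one sample
#'
#' Draws `depth` reads from the library by a multinomial with the given
#' weights, lays each draw out in the read geometry (forward mate:
#' barcode + filler + `TCC` + left core + `GAA` as its last 18 nt; reverse
#' mate: barcode + reverse complement of `ATG` + right core + `ACT` +
#' filler, so that the first 18 nt of its reverse complement are the right
#' arm), then applies substitution and N noise to both mates. Truth counts
#' are recorded before noise.
#'
#' @param library Tibble from [make_library()].
#' @param weights Tibble `key`, `weight` (e.g. from [enrich_weights()]),
#'   aligned with `library`.
#' @param sample_id Sample to emit; must appear in `config$barcode_table`.
#' @param config A [sim_config()].
#' @param depth Override of `config$depth` (used for per-sample depths).
#' @param seed Override of the per-sample seed; by default derived
#'   deterministically from `config$seed` and the sample's position in the
#'   barcode table.
#' @return List with `reads` (tibble `read_id`, `fwd_seq`, `rev_seq`) and
#'   `truth` (tibble `element_key`, `sample_id`, `count`, `weight`; rows
#'   with count > 0, counts summing to `depth`).
#' @export
emit_reads <- function(library, weights, sample_id, config,
                       depth = config$depth, seed = NULL) {
  bt <- config$barcode_table
  idx <- match(sample_id, bt$sample_id)
  if (is.na(idx)) {
    stop(sprintf("sample \"%s\" not in barcode table", sample_id), call. = FALSE)
  }
  barcode <- bt$barcode[idx]
  bl <- nchar(barcode)
  if (config$read_length < bl + 18L) {
    stop("read_length too short for barcode + 18-nt arm window", call. = FALSE)
  }
  if (is.null(seed)) seed <- (config$seed + 7919L * idx) %% .Machine$integer.max
  stopifnot(nrow(weights) == nrow(library), all(weights$key == library$key))

  empty <- list(
    reads = tibble::tibble(read_id = character(), fwd_seq = character(),
                           rev_seq = character()),
    truth = tibble::tibble(element_key = character(), sample_id = character(),
                           count = integer(), weight = double())
  )
  if (depth == 0L || nrow(library) == 0L) return(empty)

  withr::with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, depth, prob = weights$weight))
    drawn <- counts > 0L
    truth <- tibble::tibble(
      element_key = library$key[drawn],
      sample_id = sample_id,
      count = counts[drawn],
      weight = weights$weight[drawn]
    )
    ord <- rep(which(drawn), counts[drawn])
    pad <- fill_seq(config$filler, config$read_length - bl - 18L)
    fwd <- paste0(barcode, pad, "TCC", library$left_core[ord], "GAA")
    rev_arm <- paste0("ATG", library$right_core[ord], "ACT", pad)
    rev <- paste0(barcode, revcomp(rev_arm))
    fwd <- apply_noise(fwd, config$error_rate, config$n_rate)
    rev <- apply_noise(rev, config$error_rate, config$n_rate)
    list(
      reads = tibble::tibble(
        read_id = sprintf("%s_%07d", sample_id, seq_along(ord)),
        fwd_seq = fwd, rev_seq = rev
      ),
      truth = truth
    )
  })
}

#' Simulate a full multi-sample screen
#'
#' Generates the library once, derives per-sample sampling weights as the
#' planted-motif weight raised to each sample's enrichment-round count, and
#' emits reads for every sample in the barcode table. All randomness derives
#' from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `library`, `reads` (one multiplexed tibble over all
#'   samples, with a `sample_id` truth column), and `truth` (combined truth
#'   table).
#' @seealso [write_simulation()] to serialise to FASTQ/TSV.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lib <- make_library(config$n_elements, seed = config$seed)
  base_w <- enrich_weights(lib, config$planted_motifs)
  per_sample <- purrr::map(seq_len(nrow(config$barcode_table)), function(i) {
    sid <- config$barcode_table$sample_id[i]
    rounds <- config$barcode_table$rounds[i]
    w <- base_w
    w$weight <- w$weight^rounds
    res <- emit_reads(lib, w, sid, config)
    res$reads$sample_id <- sid
    res
  })
  list(
    library = lib,
    reads = dplyr::bind_rows(purrr::map(per_sample, "reads")),
    truth = dplyr::bind_rows(purrr::map(per_sample, "truth"))
  )
}

#' Write a simulated screen to disk
#'
#' Serialises the multiplexed reads as a FASTQ (constant quality `I`) or
#' FASTA mate pair, the truth table and barcode table as TSV, and the
#' configuration as YAML.
#'
#' @param sim Result of [simulate_screen()].
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @param format `"fastq"` or `"fasta"`.
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulation <- function(sim, config, dir, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- format
  paths <- list(
    fwd = file.path(dir, paste0("reads_R1.", ext)),
    rev = file.path(dir, paste0("reads_R2.", ext)),
    truth = file.path(dir, "truth.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    config = file.path(dir, "sim_config.yaml")
  )
  write_read_pairs(sim$reads, paths$fwd, paths$rev, format = format)
  readr::write_tsv(sim$truth, paths$truth)
  readr::write_tsv(config$barcode_table[c("sample_id", "barcode")],
                   paths$barcodes)
  cfg <- config
  class(cfg) <- NULL
  cfg$barcode_table <- as.data.frame(cfg$barcode_table)
  cfg$planted_motifs <- as.data.frame(cfg$planted_motifs)
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
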