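# Pipeline orchestration and the summary table: one row per sample with
# raw/filtered/unique counts, % unique, cluster count and % clustered —
# the per-sample complexity statistics that reveal enrichment.

#' Summary rows from per-sample counts
#'
#' Computes the derived percentage statistics from the raw bookkeeping
#' numbers: `pct_unique = 100 * n_unique / n_filtered` and
#' `pct_clustered = 100 * (n_unique - n_clusters) / n_unique`, both
#' rounded half-up to one decimal.
#'
#' @param counts Tibble with columns `sample_id`, `n_raw`, `n_filtered`,
#'   `n_unique`, `n_clusters`.
#' @return Tibble with those columns plus `pct_unique` and
#'   `pct_clustered`, ordered as the input.
#' @examples
#' summarize_counts(tibble::tibble(
#'   sample_id = "S4", n_raw = 481873, n_filtered = 299152,
#'   n_unique = 82834, n_clusters = 44055))
#' @export
summarize_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("sample_id", "n_raw", "n_filtered", "n_unique", "n_clusters")
  if (!all(need %in% names(counts))) {
    stop("`counts` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts |>
    dplyr::mutate(
      pct_unique = purrr::map2_dbl(.data$n_unique, .data$n_filtered,
                                   pct_unique.numeric),
      pct_clustered = purrr::map2_dbl(.data$n_unique, .data$n_clusters,
                                      pct_clustered.numeric)
    ) |>
    dplyr::select(dplyr::all_of(c(need[1:4])), "pct_unique", "n_clusters",
                  "pct_clustered")
}

#' Summary table over processed samples
#'
#' @param counted_samples List of `counted_sample` objects.
#' @param cluster_sets List of matching `syne_clusters` objects (same
#'   order/sample ids).
#' @return Tibble as in [summarize_counts()].
#' @export
summarize_samples <- function(counted_samples, cluster_sets) {
  if (length(counted_samples) != length(cluster_sets)) {
    stop("each counted sample needs a matching cluster set", call. = FALSE)
  }
  rows <- purrr::map2(counted_samples, cluster_sets, function(cs, cl) {
    if (!identical(attr(cs, "sample_id"), attr(cl, "sample_id"))) {
      stop("counted sample and cluster set sample ids do not match",
           call. = FALSE)
    }
    tibble::tibble(
      sample_id = attr(cs, "sample_id"),
      n_raw = attr(cs, "n_raw"),
      n_filtered = attr(cs, "n_filtered"),
      n_unique = attr(cs, "n_unique"),
      n_clusters = attr(cl, "n_clusters")
    )
  })
  summarize_counts(dplyr::bind_rows(rows))
}

#' Pipeline configuration
#'
#' @param fwd_reads,rev_reads Paths to the multiplexed mate files
#'   (FASTQ/FASTA).
#' @param barcodes Barcode table (tibble `sample_id`, `barcode`) or path to
#'   a two-column TSV.
#' @param references Named character vector mapping each ChIP sample id to
#'   the sample id of the sub-library it originated from; these pairs drive
#'   the k-mer enrichment stage.
#' @param k Window lengths for k-mer counting (default `5:7`).
#' @param pseudocount Pseudocount for enrichment ratios (default 1).
#' @param motif_db Motif TSV path (default: bundled demo table).
#' @param top_anchors Number of top representatives per ChIP sample whose
#'   cores seed the coupled-partner export (default 3).
#' @param out_dir Output directory for all artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fwd_reads, rev_reads, barcodes, references,
                            k = 5:7, pseudocount = 1,
                            motif_db = demo_motif_db(), top_anchors = 3L,
                            out_dir = "synescreen_out") {
  if (is.character(barcodes) && length(barcodes) == 1L) {
    barcodes <- readr::read_tsv(barcodes, col_types = "cc")
  }
  barcodes <- tibble::as_tibble(barcodes)
  references <- unlist(references)
  bad <- setdiff(c(names(references), unname(references)),
                 barcodes$sample_id)
  if (length(bad) > 0) {
    stop("reference map names samples absent from the barcode table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    fwd_reads = fwd_reads, rev_reads = rev_reads, barcodes = barcodes,
    references = references, k = as.integer(k), pseudocount = pseudocount,
    motif_db = motif_db, top_anchors = as.integer(top_anchors),
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `barcodes` may be a
#' path or an inline table.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.list(y$barcodes) || is.data.frame(y$barcodes)) {
    y$barcodes <- tibble::as_tibble(as.data.frame(y$barcodes))
  }
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Demultiplex -> extract -> tally -> cluster -> k-mer enrichment (each
#' ChIP sample against its configured source sub-library) -> coupled-core
#' export -> motif annotation -> summary. All artifacts are written as TSV
#' (plus MEME-input FASTA) under `config$out_dir`, together with a run log
#' recording parameters and per-stage counts. Reruns with the same config
#' and inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `counted` (per-sample `counted_sample`s),
#'   `clusters`, `summary`, `enrichment`, `venn`, `annotations`, and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(
    "synescreen run log",
    sprintf("package version: %s", as.character(utils::packageVersion("synescreen"))),
    sprintf("k: %s; pseudocount: %g; top_anchors: %d",
            paste(config$k, collapse = ","), config$pseudocount,
            config$top_anchors),
    sprintf("motif_db: %s", basename(config$motif_db))
  )
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage \"%s\" failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  pairs <- stage("read", read_read_pairs(config$fwd_reads, config$rev_reads))
  note("read: %d read pairs", nrow(pairs))

  demuxed <- stage("demux", demultiplex(pairs, config$barcodes))
  note("demux: %d assigned, %d unassigned", nrow(demuxed),
       attr(demuxed, "n_unassigned"))

  sample_ids <- config$barcodes$sample_id
  by_sample <- split(demuxed, factor(demuxed$sample_id, levels = sample_ids))

  counted <- list()
  rejections <- list()
  for (sid in sample_ids) {
    d <- by_sample[[sid]]
    ex <- stage("extract", extract_synes(d))
    counted[[sid]] <- stage("tally", tally_synes(ex, sid, n_raw = nrow(d)))
    rej <- rejection_summary(ex)
    rej$sample_id <- sid
    rejections[[sid]] <- rej
    note("extract %s: %d assigned -> %d SynEs (%d unique)", sid, nrow(d),
         attr(counted[[sid]], "n_filtered"), attr(counted[[sid]], "n_unique"))
    write_counts(counted[[sid]], file.path(out_dir, sprintf("counts_%s.tsv", sid)))
  }
  readr::write_tsv(dplyr::bind_rows(rejections)[c("sample_id", "reason", "n")],
                   file.path(out_dir, "rejections.tsv"))

  clusters <- purrr::map(counted, function(cs) stage("cluster", build_clusters(cs)))
  for (sid in sample_ids) {
    cl <- clusters[[sid]]
    note("cluster %s: %d unique -> %d clusters", sid,
         attr(cl, "n_unique_input"), attr(cl, "n_clusters"))
    per_member <- tibble::as_tibble(cl) |>
      dplyr::left_join(cluster_table(cl)[c("root_key", "cumulative")],
                       by = "root_key") |>
      dplyr::transmute(sample_id = sid, root_key = .data$root_key,
                       member_key = .data$key, member_count = .data$count,
                       cumulative = .data$cumulative)
    readr::write_tsv(per_member,
                     file.path(out_dir, sprintf("clusters_%s.tsv", sid)))
  }
  reps_tbl <- purrr::imap(clusters, function(cl, sid) {
    dplyr::mutate(representatives(cl), sample_id = sid, .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_tsv(reps_tbl, file.path(out_dir, "representatives.tsv"))

  chip_ids <- names(config$references)
  venn <- NULL
  if (length(chip_ids) >= 2) {
    venn <- common_representatives(clusters[chip_ids])
    flat <- venn |>
      dplyr::mutate(keys = purrr::map_chr(.data$keys, paste, collapse = ",")) |>
      dplyr::select("samples", "n_samples", "n_keys", "keys")
    readr::write_tsv(flat, file.path(out_dir, "venn_partition.tsv"))
  }

  enrichment <- list()
  for (sid in chip_ids) {
    ref <- config$references[[sid]]
    for (k in config$k) {
      er <- stage("kmer", enrichment_ratio(
        count_kmers(counted[[sid]], k),
        count_kmers(counted[[ref]], k),
        pseudocount = config$pseudocount))
      enrichment[[sprintf("%s_k%d", sid, k)]] <- er
      readr::write_tsv(tibble::as_tibble(er),
                       file.path(out_dir, sprintf("kmer_%s_vs_%s_k%d.tsv",
                                                  sid, ref, k)))
      note("kmer %s vs %s (k=%d): top %s ratio %.3f", sid, ref, k,
           er$kmer[1], er$ratio[1])
    }
  }

  for (sid in chip_ids) {
    top <- representatives(clusters[[sid]], top_n = config$top_anchors)
    if (nrow(top) == 0) next
    partners <- purrr::map(top$root_key, function(key) {
      coupled_partners(counted[[sid]], substr(key, 1L, 12L), side = "left")
    })
    flat <- purrr::map2(partners, top$root_key, function(p, key) {
      if (nrow(p) == 0) return(NULL)
      tibble::tibble(sample_id = sid, anchor = attr(p, "anchor"),
                     side = attr(p, "side"), partner_core = p$partner_core,
                     count = p$count)
    }) |> dplyr::bind_rows()
    readr::write_tsv(flat, file.path(out_dir, sprintf("coupled_%s.tsv", sid)))
    keep <- purrr::map_int(partners, nrow) > 0
    if (any(keep)) {
      export_meme_fasta(partners[keep],
                        file.path(out_dir, sprintf("meme_input_%s.fasta", sid)))
    }
  }

  motifs <- stage("motifs", read_motif_db(config$motif_db))
  annotations <- purrr::imap(clusters, function(cl, sid) {
    if (attr(cl, "n_unique_input") == 0) return(NULL)
    dplyr::mutate(annotate_representatives(cl, motifs), sample_id = sid,
                  .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_tsv(annotations, file.path(out_dir, "annotations.tsv"))

  summary <- summarize_samples(counted, clusters)
  readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(
    counted = counted, clusters = clusters, summary = summary,
    enrichment = enrichment, venn = venn, annotations = annotations,
    paths = out_dir
  ))
}
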