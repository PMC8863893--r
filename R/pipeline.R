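# End-to-end orchestration: readproc -> consensus -> cOTU -> quantify,
# with a serializable configuration and a QC report.

#' Pipeline configuration
#'
#' All thresholds of the processing pipeline with their documented
#' defaults. The configuration is serialized into the output manifest so a
#' run can be reproduced bit-identically.
#'
#' @param max_tag_mismatch Barcode fixed-tag mismatches tolerated (1).
#' @param reject_ambiguous Reject barcodes with N in the random part (TRUE).
#' @param barcode_max_edit Levenshtein threshold for barcode clustering (2).
#' @param min_overlap Minimum read-pair overlap, bases (30).
#' @param max_overlap_mismatch_frac Maximum mismatch fraction in the
#'   overlap (0.1).
#' @param max_intra_distance Within-barcode 16S clustering distance (0:
#'   exact sequence types, preserving single-base resolution).
#' @param min_reads_per_repseq Minimum reads behind a RepSeq (3).
#' @param min_cell_support Minimum barcode clusters behind a Bar
#'   sequence (2).
#' @param min_minor_fraction Minimum support relative to the dominant
#'   RepSeq of the same barcode (0.1).
#' @param alpha_fdr FDR level of the co-occurrence linkage test (0.05).
#' @param min_co_fraction Minimum co-detection fraction for linkage (0.5).
#' @param mode `"cell"` (count cells per cOTU) or `"ecdna"` (count DNA
#'   fragments per Bar sequence).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_tag_mismatch = 1L,
                            reject_ambiguous = TRUE,
                            barcode_max_edit = 2L,
                            min_overlap = 30L,
                            max_overlap_mismatch_frac = 0.1,
                            max_intra_distance = 0L,
                            min_reads_per_repseq = 3L,
                            min_cell_support = 2L,
                            min_minor_fraction = 0.1,
                            alpha_fdr = 0.05,
                            min_co_fraction = 0.5,
                            mode = c("cell", "ecdna")) {
  structure(list(max_tag_mismatch = max_tag_mismatch,
                 reject_ambiguous = reject_ambiguous,
                 barcode_max_edit = barcode_max_edit,
                 min_overlap = min_overlap,
                 max_overlap_mismatch_frac = max_overlap_mismatch_frac,
                 max_intra_distance = max_intra_distance,
                 min_reads_per_repseq = min_reads_per_repseq,
                 min_cell_support = min_cell_support,
                 min_minor_fraction = min_minor_fraction,
                 alpha_fdr = alpha_fdr,
                 min_co_fraction = min_co_fraction,
                 mode = match.arg(mode)),
            class = "pipeline_config")
}

.empty_pipeline_result <- function(config) {
  list(bar_sequences = data.frame(bar_id = character(0), sequence = character(0),
                                  n_barcodes = integer(0)),
       assignment = data.frame(barcode_cluster_id = character(0),
                               bar_id = character(0), read_support = integer(0)),
       cotus = data.frame(cotu_id = character(0), bar_id = character(0),
                          sequence = character(0), n_barcodes = integer(0)),
       counts = data.frame(cotu_id = character(0), cell_count = integer(0)),
       pairs = data.frame(), clusters = data.frame(), repseqs = data.frame(),
       abundance = NULL, config = config,
       qc = list(reads_total = 0L, reads_accepted = 0L, reads_merged = 0L,
                 n_barcode_clusters = 0L))
}

#' Run the full processing pipeline on a sequenced (or simulated) run
#'
#' Executes barcode extraction and clustering, pair merging,
#' within-barcode 16S clustering and RepSeq calling, error filtering,
#' co-occurrence grouping into cOTUs and cell counting; optionally anchors
#' counts to an external total abundance and applies a contamination
#' control. In `"ecdna"` mode the barcode-linked sequences are counted as
#' DNA fragments per Bar sequence instead of cells per cOTU.
#'
#' @param r1_path,i1_path,r2_path The three synchronized FASTQ files.
#' @param config A [pipeline_config()].
#' @param total Optional [total_abundance()] anchoring absolute abundances.
#' @param control_abs Optional named vector of control absolute abundances
#'   for the contamination filter.
#' @param cotu_map Optional cell-sample cOTU membership (`cotu_id`,
#'   `sequence`) used to roll fragments up to cOTUs in `"ecdna"` mode.
#' @param out_dir Optional output directory: Bar sequence FASTA + TSVs,
#'   cOTU/count/abundance TSVs, pair-test audit TSV, QC report and a YAML
#'   manifest are written there.
#' @return List with `bar_sequences`, `assignment`, `cotus`, `counts`,
#'   `pairs`, `clusters`, `repseqs`, `abundance` (or `fragments` in ecdna
#'   mode), `qc` and `config`.
#' @export
run_pipeline <- function(r1_path, i1_path, r2_path,
                         config = pipeline_config(),
                         total = NULL, control_abs = NULL, cotu_map = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  triplets <- parse_run(r1_path, i1_path, r2_path)
  if (!nrow(triplets)) {
    warning("empty run: no reads in input FASTQ files")
    res <- .empty_pipeline_result(config)
    if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
    return(res)
  }

  # Stage 1: barcodes
  bc <- extract_barcodes(triplets$r1, max_tag_mismatch = config$max_tag_mismatch,
                         reject_ambiguous = config$reject_ambiguous)
  acc <- which(bc$accepted)
  clustering <- cluster_barcodes(bc$random[acc],
                                 max_edit_distance = config$barcode_max_edit)

  # Stage 2: merge pairs
  merged <- merge_pairs(triplets[acc, , drop = FALSE],
                        min_overlap = config$min_overlap,
                        max_overlap_mismatch_frac = config$max_overlap_mismatch_frac)
  ok <- merged$merged
  amp <- data.frame(cluster = clustering$read_cluster[ok],
                    sequence = merged$sequence[ok],
                    quality = merged$quality[ok],
                    stringsAsFactors = FALSE)

  # Stage 3: within-barcode clustering + RepSeq calling
  repseqs <- .call_all_repseqs(amp, config$max_intra_distance)

  # Stage 4: error filtering -> Bar sequences
  fe <- filter_errors(repseqs,
                      min_reads_per_repseq = config$min_reads_per_repseq,
                      min_cell_support = config$min_cell_support,
                      min_minor_fraction = config$min_minor_fraction)

  qc <- list(reads_total = nrow(triplets),
             reads_accepted = length(acc),
             reads_merged = sum(ok),
             n_barcode_clusters = nrow(clustering$clusters),
             reads_per_barcode = unname(summary(clustering$clusters$size)),
             barcode_collision_expectation =
               choose(nrow(clustering$clusters), 2) / 4^24,
             n_repseqs = nrow(repseqs),
             n_bar_sequences = nrow(fe$bar_sequences))

  if (!nrow(fe$bar_sequences)) {
    res <- .empty_pipeline_result(config)
    res$qc <- qc
    res$clusters <- clustering$clusters
    res$repseqs <- repseqs
    if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
    return(res)
  }

  # Stage 5: cOTU grouping
  pairs <- cooccurrence_table(fe$assignment)
  pairs <- link_test(pairs, alpha_fdr = config$alpha_fdr,
                     min_co_fraction = config$min_co_fraction)
  cotus <- build_cotus(fe$bar_sequences, pairs)
  qc$n_linked_pairs <- sum(pairs$linked)
  qc$n_cotus <- length(unique(cotus$cotu_id))

  res <- list(bar_sequences = fe$bar_sequences,
              assignment = fe$assignment,
              cotus = cotus,
              pairs = pairs,
              clusters = clustering$clusters,
              repseqs = repseqs,
              config = config,
              qc = qc)

  if (config$mode == "cell") {
    res$counts <- count_cells(fe$assignment, cotus)
    if (!is.null(total)) {
      counts <- stats::setNames(res$counts$cell_count, res$counts$cotu_id)
      abs_tab <- absolute_abundance(counts, total)
      if (!is.null(control_abs)) {
        cf <- contamination_filter(abs_tab, control_abs)
        res$abundance <- cf$filtered
        res$contamination_removed <- cf$removed
      } else {
        res$abundance <- abs_tab
      }
      res$relative_abundance <- counts / sum(counts)
    }
  } else {
    res$fragments <- quantify_fragments(fe$assignment, fe$bar_sequences,
                                        cotu_map = cotu_map, total = total)
    res$counts <- data.frame(cotu_id = character(0), cell_count = integer(0))
  }

  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

# Within-barcode grouping and RepSeq calling over all barcode clusters.
.call_all_repseqs <- function(amp, max_intra_distance) {
  if (!nrow(amp)) {
    return(data.frame(barcode_cluster_id = character(0), sequence = character(0),
                      read_support = integer(0), mean_quality = numeric(0),
                      stringsAsFactors = FALSE))
  }
  by_bc <- split(seq_len(nrow(amp)), amp$cluster)
  rows <- lapply(names(by_bc), function(bcid) {
    idx <- by_bc[[bcid]]
    grp <- cluster_within_barcode(amp$sequence[idx], max_intra_distance)
    reps <- lapply(split(idx, grp), function(gi) {
      call_repseq(amp$sequence[gi], amp$quality[gi])
    })
    data.frame(barcode_cluster_id = bcid,
               sequence = vapply(reps, `[[`, character(1), "sequence"),
               read_support = vapply(reps, `[[`, integer(1), "read_support"),
               mean_quality = vapply(reps, `[[`, numeric(1), "mean_quality"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tw <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (nrow(res$bar_sequences)) {
    x <- Biostrings::DNAStringSet(res$bar_sequences$sequence)
    names(x) <- res$bar_sequences$bar_id
    Biostrings::writeXStringSet(x, file.path(out_dir, "bar_sequences.fasta"))
  }
  tw(res$bar_sequences, "bar_sequences.tsv")
  tw(res$assignment, "cell_assignment.tsv")
  tw(res$cotus, "cotus.tsv")
  if (!is.null(res$pairs) && nrow(res$pairs)) tw(res$pairs, "pair_tests.tsv")
  tw(res$counts, "counts.tsv")
  if (!is.null(res$abundance)) {
    tw(data.frame(cotu_id = names(res$abundance),
                  abundance = as.numeric(res$abundance)),
       "abundance.tsv")
  }
  manifest <- list(config = unclass(res$config), qc = res$qc)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(NULL)
}
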