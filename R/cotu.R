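# Stages 5-6: group Bar sequences into cell-based OTUs (cOTUs) by testing
# droplet co-occurrence against the independent-encapsulation null, then
# count cells per cOTU.

#' Pairwise co-occurrence of Bar sequences across barcode clusters
#'
#' One record per unordered pair of Bar sequences observed together in at
#' least one barcode cluster, with the per-sequence barcode counts, the
#' observed co-detections and the independence expectation
#' n_i n_j / N (N = barcode clusters in the assignment).
#'
#' @param assignment Cell assignment data.frame (`barcode_cluster_id`,
#'   `bar_id`) from [filter_errors()].
#' @return data.frame with `bar_i`, `bar_j`, `n_i`, `n_j`, `n_co`,
#'   `expected_co`; attribute `n_total` holds N.
#' @export
cooccurrence_table <- function(assignment) {
  if (!nrow(assignment)) stop("empty cell assignment")
  assignment <- unique(assignment[, c("barcode_cluster_id", "bar_id")])
  N <- length(unique(assignment$barcode_cluster_id))
  n_bar <- table(assignment$bar_id)
  by_bc <- split(assignment$bar_id, assignment$barcode_cluster_id)
  multi <- by_bc[lengths(by_bc) >= 2L]
  out <- data.frame(bar_i = character(0), bar_j = character(0),
                    n_i = integer(0), n_j = integer(0), n_co = integer(0),
                    expected_co = numeric(0), stringsAsFactors = FALSE)
  if (length(multi)) {
    pair_list <- lapply(multi, function(b) {
      b <- sort(unique(b))
      cmb <- utils::combn(b, 2L)
      paste(cmb[1L, ], cmb[2L, ], sep = "\r")
    })
    pc <- table(unlist(pair_list, use.names = FALSE))
    ij <- strsplit(names(pc), "\r", fixed = TRUE)
    bar_i <- vapply(ij, `[[`, character(1), 1L)
    bar_j <- vapply(ij, `[[`, character(1), 2L)
    out <- data.frame(bar_i = bar_i, bar_j = bar_j,
                      n_i = as.integer(n_bar[bar_i]),
                      n_j = as.integer(n_bar[bar_j]),
                      n_co = as.integer(pc),
                      stringsAsFactors = FALSE)
    out$expected_co <- coencapsulation_expectation(out$n_i, out$n_j, N)
    out <- out[order(out$bar_i, out$bar_j), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_total") <- N
  out
}

#' Test co-occurring pairs against the independent-encapsulation null
#'
#' For each pair the upper-tail exact binomial p-value
#' P(X >= n_co), X ~ Binomial(n_max, n_min / N) (n_max/n_min the larger and
#' smaller barcode counts) is computed, Benjamini-Hochberg adjusted across
#' all tested pairs, and a pair is linked when the adjusted p-value is
#' below `alpha_fdr` AND the co-detection fraction n_co / min(n_i, n_j)
#' reaches `min_co_fraction`. Variants of a multi-copy genome co-occur in
#' nearly every droplet holding the cell; incidental co-encapsulations do
#' not.
#'
#' @param pairs Output of [cooccurrence_table()].
#' @param alpha_fdr FDR level for linkage. Default 0.05.
#' @param min_co_fraction Minimum co-detection fraction. Default 0.5.
#' @return `pairs` with `p_value`, `adjusted_p`, `co_fraction`, `linked`.
#' @export
link_test <- function(pairs, alpha_fdr = 0.05, min_co_fraction = 0.5) {
  N <- attr(pairs, "n_total")
  if (is.null(N) || !is.numeric(N) || N <= 0) {
    stop("pairs must carry a positive 'n_total' attribute (from cooccurrence_table)")
  }
  if (!nrow(pairs)) {
    pairs$p_value <- numeric(0); pairs$adjusted_p <- numeric(0)
    pairs$co_fraction <- numeric(0); pairs$linked <- logical(0)
    return(pairs)
  }
  n_max <- pmax(pairs$n_i, pairs$n_j)
  n_min <- pmin(pairs$n_i, pairs$n_j)
  pairs$p_value <- stats::pbinom(pairs$n_co - 1L, n_max, n_min / N,
                                 lower.tail = FALSE)
  pairs$adjusted_p <- stats::p.adjust(pairs$p_value, method = "BH")
  pairs$co_fraction <- pairs$n_co / n_min
  pairs$linked <- pairs$adjusted_p < alpha_fdr &
    pairs$co_fraction >= min_co_fraction
  pairs
}

#' Group Bar sequences into cOTUs
#'
#' Connected components over the linkage graph (Bar sequences as vertices,
#' linked pairs as edges); unlinked sequences become singleton cOTUs.
#' cOTU ids are assigned by descending total barcode support of the
#' members, then lexicographically.
#'
#' @param bar_sequences data.frame from [filter_errors()] (`bar_id`,
#'   `sequence`, `n_barcodes`).
#' @param pairs Tested pairs from [link_test()] (may have zero rows).
#' @return data.frame with one row per Bar sequence: `cotu_id`, `bar_id`,
#'   `sequence`, `n_barcodes`.
#' @export
build_cotus <- function(bar_sequences, pairs) {
  stopifnot(nrow(bar_sequences) >= 1L)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(bar_sequences),
                            name = bar_sequences$bar_id)
  if (nrow(pairs)) {
    linked <- pairs[pairs$linked, , drop = FALSE]
    if (nrow(linked)) {
      g <- igraph::add_edges(g, rbind(linked$bar_i, linked$bar_j))
    }
  }
  comp <- igraph::components(g)$membership
  comp <- comp[bar_sequences$bar_id]
  support <- tapply(bar_sequences$n_barcodes, comp, sum)
  first_bar <- tapply(bar_sequences$bar_id, comp, min)
  comp_ids <- names(support)
  ord <- order(-as.numeric(support), first_bar, method = "radix")
  labels <- stats::setNames(character(length(comp_ids)), comp_ids[ord])
  labels[comp_ids[ord]] <- sprintf("cOTU%04d", seq_along(comp_ids))
  out <- data.frame(cotu_id = unname(labels[as.character(comp)]),
                    bar_id = bar_sequences$bar_id,
                    sequence = bar_sequences$sequence,
                    n_barcodes = bar_sequences$n_barcodes,
                    stringsAsFactors = FALSE)
  out[order(out$cotu_id, out$bar_id), , drop = FALSE]
}

#' Count cells per cOTU
#'
#' A cell is one barcode cluster linked to a cOTU: a barcode containing
#' several Bar sequences of one cOTU (a multi-copy genome) contributes one
#' cell; a barcode containing Bar sequences of k distinct cOTUs
#' (co-encapsulated cells, distinguishable by their 16S sequences)
#' contributes one cell to each of the k cOTUs.
#'
#' @param assignment Cell assignment (`barcode_cluster_id`, `bar_id`).
#' @param cotus Membership table from [build_cotus()].
#' @return data.frame `cotu_id`, `cell_count`, sorted by cOTU id.
#' @export
count_cells <- function(assignment, cotus) {
  orphan <- setdiff(assignment$bar_id, cotus$bar_id)
  if (length(orphan)) {
    stop("bar ids in assignment without a cOTU: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  m <- unique(data.frame(
    barcode_cluster_id = assignment$barcode_cluster_id,
    cotu_id = cotus$cotu_id[match(assignment$bar_id, cotus$bar_id)],
    stringsAsFactors = FALSE))
  tab <- table(m$cotu_id)
  out <- data.frame(cotu_id = names(tab), cell_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$cotu_id), , drop = FALSE]
}
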