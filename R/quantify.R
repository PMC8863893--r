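# Stages 7-8: anchor sequencing-determined counts to an externally measured
# total abundance, remove contaminant cOTUs via a control, and fragment-mode
# quantification for extracellular DNA.

#' Total-abundance measurement of a sample
#'
#' The external anchor for absolute quantification: total cells (or ecDNA
#' fragments) per unit weight or volume, typically measured by droplet
#' digital PCR. Totals are inputs; they are never inferred from sequencing
#' depth.
#'
#' @param sample_id Sample label.
#' @param value Items per unit (>= 0).
#' @param unit Unit label, e.g. `"cells/mg"`, `"cells/ul"`, `"fragments/mg"`.
#' @param method Measurement method label.
#' @return An object of class `total_abundance`.
#' @export
total_abundance <- function(sample_id, value, unit = "cells/mg",
                            method = "ddPCR") {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  structure(list(sample_id = as.character(sample_id), value = value,
                 unit = unit, method = method),
            class = "total_abundance")
}

.total_value <- function(total) {
  if (inherits(total, "total_abundance")) total$value
  else if (is.numeric(total) && length(total) == 1L && total >= 0) total
  else stop("expected a total_abundance or a single non-negative number")
}

#' Convert cOTU cell counts to absolute abundances
#'
#' abs_i = count_i / sum(counts) * total, i.e. counts are turned into
#' proportions and scaled by the externally measured total abundance of the
#' sample. Scale-invariant in the counts and linear in the total.
#'
#' @param counts Named numeric vector of cell (or fragment) counts.
#' @param total A [total_abundance()] or a single number.
#' @return Named numeric vector of absolute abundances, same units as the
#'   total.
#' @examples
#' absolute_abundance(c(a = 30, b = 70), 1e9)
#' @export
absolute_abundance <- function(counts, total) {
  if (sum(counts) <= 0) stop("total counts must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts / sum(counts) * .total_value(total)
}

#' Remove contaminant cOTUs identified by a control sample
#'
#' A cOTU is flagged when its absolute abundance in the control (processed
#' through the identical pipeline) is at least `max_control_fraction` of
#' its abundance in the sample; flagged cOTUs are removed and listed. With
#' an empty control nothing is removed; the filter is idempotent.
#'
#' @param sample_abs Named numeric vector of sample absolute abundances.
#' @param control_abs Named numeric vector of control absolute abundances
#'   (may be empty or NULL; a warning is issued and the sample passes
#'   through).
#' @param max_control_fraction Flagging threshold. Default 0.1.
#' @return List with `filtered` (sample vector without flagged cOTUs) and
#'   `removed` (data.frame `cotu_id`, `sample_abundance`,
#'   `control_abundance`).
#' @export
contamination_filter <- function(sample_abs, control_abs,
                                 max_control_fraction = 0.1) {
  removed <- data.frame(cotu_id = character(0), sample_abundance = numeric(0),
                        control_abundance = numeric(0), stringsAsFactors = FALSE)
  if (is.null(control_abs) || !length(control_abs)) {
    warning("no control supplied; contamination filter passes all cOTUs through")
    return(list(filtered = sample_abs, removed = removed))
  }
  ctrl <- control_abs[match(names(sample_abs), names(control_abs))]
  ctrl[is.na(ctrl)] <- 0
  flag <- ctrl >= max_control_fraction * sample_abs & sample_abs > 0
  if (any(flag)) {
    removed <- data.frame(cotu_id = names(sample_abs)[flag],
                          sample_abundance = unname(sample_abs[flag]),
                          control_abundance = unname(ctrl[flag]),
                          stringsAsFactors = FALSE)
  }
  list(filtered = sample_abs[!flag], removed = removed)
}

#' Quantify ecDNA fragments per Bar sequence and per cOTU
#'
#' In fragment mode each (barcode cluster, Bar sequence) link is one DNA
#' fragment, not one cell. Fragment counts are reported per Bar sequence
#' and, when a cOTU map determined from cell-samples is supplied, rolled up
#' to those cOTUs; Bar sequences absent from the map are reported as
#' unassigned (they do not define cOTUs because fragments are not cells).
#' With a total fragment abundance, absolute abundances are attached; when
#' a matching cell abundance table is given, the per-cOTU ecDNA/cell ratio
#' is emitted.
#'
#' @param assignment Fragment-mode cell assignment (`barcode_cluster_id`,
#'   `bar_id`).
#' @param bar_sequences Fragment-mode Bar sequence table (`bar_id`,
#'   `sequence`).
#' @param cotu_map Optional cOTU membership from a cell-sample run
#'   (`cotu_id`, `sequence`); matched by sequence identity.
#' @param total Optional [total_abundance()] in fragments per unit.
#' @param cell_abundance Optional named vector of per-cOTU absolute cell
#'   abundances for the ratio.
#' @return List with `per_bar` (data.frame `bar_id`, `sequence`,
#'   `fragment_count`, `cotu_id` (NA when unassigned), optionally
#'   `abundance`), `per_cotu` (rolled-up counts/abundance, NULL without a
#'   map), `unassigned` (bar ids without a cOTU) and `ratio` (per-cOTU
#'   ecDNA/cell, NULL unless both abundances available).
#' @export
quantify_fragments <- function(assignment, bar_sequences, cotu_map = NULL,
                               total = NULL, cell_abundance = NULL) {
  counts <- table(unique(assignment[, c("barcode_cluster_id", "bar_id")])$bar_id)
  per_bar <- data.frame(bar_id = bar_sequences$bar_id,
                        sequence = bar_sequences$sequence,
                        fragment_count = as.integer(counts[bar_sequences$bar_id]),
                        stringsAsFactors = FALSE)
  per_bar$fragment_count[is.na(per_bar$fragment_count)] <- 0L
  per_bar$cotu_id <- NA_character_
  per_cotu <- NULL
  if (!is.null(cotu_map)) {
    per_bar$cotu_id <- cotu_map$cotu_id[match(per_bar$sequence,
                                              cotu_map$sequence)]
    assigned <- per_bar[!is.na(per_bar$cotu_id), , drop = FALSE]
    if (nrow(assigned)) {
      agg <- tapply(assigned$fragment_count, assigned$cotu_id, sum)
      per_cotu <- data.frame(cotu_id = names(agg),
                             fragment_count = as.integer(agg),
                             stringsAsFactors = FALSE)
    } else {
      per_cotu <- data.frame(cotu_id = character(0),
                             fragment_count = integer(0),
                             stringsAsFactors = FALSE)
    }
  }
  if (!is.null(total) && sum(per_bar$fragment_count) > 0) {
    per_bar$abundance <- absolute_abundance(per_bar$fragment_count, total)
    if (!is.null(per_cotu) && nrow(per_cotu)) {
      per_cotu$abundance <- per_cotu$fragment_count /
        sum(per_bar$fragment_count) * .total_value(total)
    }
  }
  ratio <- NULL
  if (!is.null(per_cotu) && !is.null(per_cotu$abundance) &&
      !is.null(cell_abundance)) {
    common <- intersect(per_cotu$cotu_id, names(cell_abundance))
    common <- common[cell_abundance[common] > 0]
    if (length(common)) {
      ratio <- stats::setNames(
        per_cotu$abundance[match(common, per_cotu$cotu_id)] /
          as.numeric(cell_abundance[common]),
        common)
    }
  }
  list(per_bar = per_bar,
       per_cotu = per_cotu,
       unassigned = per_bar$bar_id[is.na(per_bar$cotu_id)],
       ratio = ratio)
}
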