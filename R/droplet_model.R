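#' barbiq: cell-based 16S identification and quantification from barcoded droplets
#'
#' Implements the computational core of cellularly barcoded 16S rRNA droplet
#' sequencing: Poisson droplet occupancy models, a run simulator with ground
#' truth, barcode/amplicon clustering and consensus calling, co-occurrence
#' grouping of 16S sequence variants into cell-based OTUs (cOTUs), absolute
#' abundance anchoring, and the downstream diversity/noise/differential
#' statistics of the method.
#'
#' @importFrom stats rpois rbinom rnbinom median var pbinom p.adjust qpois
#'   rmultinom setNames aggregate
#' @importFrom utils adist head tail write.table read.table
#' @keywords internal
"_PACKAGE"

#' Volume of a spherical droplet
#'
#' Converts a droplet diameter in micrometres to its volume in nanolitres
#' (pi d^3 / 6). A 120 um droplet, the nominal diameter of the emulsion
#' generator used for cellular barcoding, holds about 0.905 nl.
#'
#' @param diameter Droplet diameter in micrometres (scalar or vector, > 0).
#' @return Volume(s) in nanolitres.
#' @examples
#' droplet_volume(120) # ~0.905 nl
#' @export
droplet_volume <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) == 0 || any(!is.finite(diameter)) ||
      any(diameter <= 0)) {
    stop("'diameter' must be a positive finite number (micrometres)")
  }
  # um^3 -> nl: 1 nl = 1e6 um^3
  (pi * diameter^3 / 6) / 1e6
}

#' Encapsulation run specification
#'
#' Describes one emulsification run: droplet size, total emulsion volume and
#' the numbers of barcode molecules and cells dispersed into it. The droplet
#' volume is derived from the diameter unless `droplet_volume_override` (nl)
#' is supplied; an override is useful because instruments rarely report a
#' droplet count, only a nominal per-droplet volume.
#'
#' @param droplet_diameter Droplet diameter in micrometres. Default 120.
#' @param emulsion_volume Total aqueous volume emulsified, in microlitres.
#' @param n_barcodes Number of barcode molecules loaded.
#' @param n_cells Number of cells loaded (may be 0, e.g. barcode-only runs).
#' @param droplet_volume_override Optional droplet volume in nanolitres,
#'   taking precedence over the diameter-derived volume.
#' @return An object of class `encapsulation_spec`.
#' @examples
#' encapsulation_spec(emulsion_volume = 960, n_barcodes = 160000,
#'                    n_cells = 240000, droplet_volume_override = 0.85)
#' @export
encapsulation_spec <- function(droplet_diameter = 120, emulsion_volume,
                               n_barcodes = 0, n_cells = 0,
                               droplet_volume_override = NULL) {
  stopifnot(is.numeric(emulsion_volume), length(emulsion_volume) == 1L,
            emulsion_volume > 0)
  if (!is.null(droplet_volume_override)) {
    stopifnot(is.numeric(droplet_volume_override),
              length(droplet_volume_override) == 1L,
              droplet_volume_override > 0)
  }
  stopifnot(n_barcodes >= 0, n_cells >= 0)
  vol <- if (is.null(droplet_volume_override)) {
    droplet_volume(droplet_diameter)
  } else {
    droplet_volume_override
  }
  structure(
    list(droplet_diameter = droplet_diameter,
         emulsion_volume = emulsion_volume,
         n_barcodes = n_barcodes,
         n_cells = n_cells,
         droplet_volume = vol),
    class = "encapsulation_spec"
  )
}

#' Number of droplets in an encapsulation run
#'
#' @param spec An [encapsulation_spec()].
#' @return Expected droplet count (emulsion volume / droplet volume).
#' @export
n_droplets <- function(spec) {
  stopifnot(inherits(spec, "encapsulation_spec"))
  if (spec$droplet_volume <= 0) stop("droplet volume must be positive")
  spec$emulsion_volume * 1e3 / spec$droplet_volume # ul -> nl
}

#' Poisson occupancy model for droplet loading
#'
#' @param lam Mean number of items per droplet (lambda, >= 0).
#' @param n_droplets Droplet count the model refers to (optional).
#' @return An object of class `occupancy_model`.
#' @export
occupancy_model <- function(lam, n_droplets = NA_real_) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam))
  if (lam < 0) stop("lambda must be non-negative")
  structure(list(lam = lam, n_droplets = n_droplets), class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf("Poisson occupancy model: lambda = %.4g", x$lam))
  if (is.finite(x$n_droplets)) cat(sprintf(" over %.4g droplets", x$n_droplets))
  cat("\n")
  invisible(x)
}

#' Occupancy model from an encapsulation specification
#'
#' Derives the per-droplet Poisson mean for either the barcodes or the cells
#' of a run: lambda = item count / droplet count.
#'
#' @param spec An [encapsulation_spec()].
#' @param item `"barcode"` or `"cell"`.
#' @return An [occupancy_model()].
#' @examples
#' spec <- encapsulation_spec(emulsion_volume = 960, n_barcodes = 160000,
#'                            n_cells = 240000, droplet_volume_override = 0.85)
#' lambda_from_spec(spec, "barcode")$lam # ~0.1417
#' @export
lambda_from_spec <- function(spec, item = c("barcode", "cell")) {
  item <- match.arg(item)
  nd <- n_droplets(spec)
  n <- if (item == "barcode") spec$n_barcodes else spec$n_cells
  occupancy_model(n / nd, n_droplets = nd)
}

.lam_of <- function(model) {
  if (inherits(model, "occupancy_model")) model$lam
  else if (is.numeric(model) && length(model) == 1L) model
  else stop("expected an occupancy_model or a single numeric lambda")
}

#' Poisson occupancy probabilities
#'
#' P(k items in a droplet) for k = 0..k_max, with the residual tail mass
#' beyond `k_max` reported separately.
#'
#' @param model An [occupancy_model()] or a numeric lambda.
#' @param k_max Largest occupancy to tabulate (>= 0).
#' @return A list with `k`, `p` (probabilities for k = 0..k_max) and
#'   `tail` (P(K > k_max)).
#' @examples
#' occupancy_pmf(0.2, 3)$p[1:2] # 0.8187, 0.1637
#' @export
occupancy_pmf <- function(model, k_max) {
  lam <- .lam_of(model)
  if (lam < 0) stop("lambda must be non-negative")
  stopifnot(length(k_max) == 1L, k_max >= 0)
  k <- 0:k_max
  p <- stats::dpois(k, lam)
  list(k = k, p = p, tail = stats::ppois(k_max, lam, lower.tail = FALSE))
}

#' Fraction of occupied droplets holding exactly one item
#'
#' Under Poisson loading, P(K = 1 | K >= 1) = lambda e^-lambda / (1 - e^-lambda).
#' At the barcode load of a typical run (lambda ~ 0.14) about 93% of
#' barcode-occupied droplets are singletons; at a cell load of lambda ~ 0.21,
#' about 90%.
#'
#' @param model An [occupancy_model()] or numeric lambda (>= 0).
#' @return The singleton fraction. For lambda = 0 the limit value 1 is
#'   returned with a warning.
#' @examples
#' singleton_fraction(0.1417) # ~0.931
#' @export
singleton_fraction <- function(model) {
  lam <- .lam_of(model)
  if (lam < 0) stop("lambda must be non-negative")
  if (lam == 0) {
    warning("lambda = 0: returning the limiting singleton fraction of 1")
    return(1)
  }
  lam * exp(-lam) / (1 - exp(-lam))
}

#' Count-inflation factor from multi-item droplets
#'
#' Droplets holding more than one barcode inflate cell counts uniformly.
#' In `truncated2` mode the occupancy is truncated at two items, giving
#' p1 * 1 + (1 - p1) * 2 (e.g. 0.93 x 1 + 0.07 x 2 = 1.07); `exact` mode
#' returns the full conditional mean E(K | K >= 1) = lambda / (1 - e^-lambda).
#'
#' @param singleton_frac Fraction of occupied droplets with one item,
#'   in (0, 1]. Required for `truncated2`.
#' @param mode `"truncated2"` or `"exact"`.
#' @param model An [occupancy_model()] or lambda; required for `"exact"`.
#' @return The multiplicity factor (>= 1).
#' @examples
#' multiplicity_factor(0.93) # 1.07
#' @export
multiplicity_factor <- function(singleton_frac = NULL,
                                mode = c("truncated2", "exact"),
                                model = NULL) {
  mode <- match.arg(mode)
  if (mode == "truncated2") {
    if (is.null(singleton_frac) || !is.numeric(singleton_frac) ||
        length(singleton_frac) != 1L || singleton_frac <= 0 ||
        singleton_frac > 1) {
      stop("'singleton_frac' must be a single value in (0, 1]")
    }
    return(singleton_frac * 1 + (1 - singleton_frac) * 2)
  }
  if (is.null(model)) stop("'exact' mode requires a model (or lambda)")
  lam <- .lam_of(model)
  if (lam < 0) stop("lambda must be non-negative")
  if (lam == 0) return(1)
  lam / (1 - exp(-lam))
}

#' Expected co-detections of two sequences under independent encapsulation
#'
#' If sequence i is seen in `n_i` of `n_occupied` barcode-occupied droplets
#' and sequence j in `n_j`, independence predicts n_i * n_j / n_occupied
#' droplets containing both. This is the null expectation behind the
#' co-occurrence linkage test for multi-copy 16S genes.
#'
#' @param n_i,n_j Occupied-droplet (barcode) counts for the two sequences.
#' @param n_occupied Total occupied-barcode count (> 0).
#' @return Expected number of co-detections.
#' @examples
#' coencapsulation_expectation(100, 80, 10000) # 0.8
#' @export
coencapsulation_expectation <- function(n_i, n_j, n_occupied) {
  if (any(n_occupied <= 0)) stop("'n_occupied' must be positive")
  if (any(n_i < 0) || any(n_j < 0)) stop("counts must be non-negative")
  if (any(n_i > n_occupied) || any(n_j > n_occupied)) {
    stop("per-sequence counts cannot exceed 'n_occupied'")
  }
  n_i * n_j / n_occupied
}
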