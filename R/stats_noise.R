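# Technical-noise model, Poisson sampling envelopes, the envelope + 2-fold
# differential rule, and the PCR-error accumulation simulator.

#' Technical noise of replicate counts against the Poisson expectation
#'
#' Replicates are first depth-equalized by random subsampling (without
#' replacement) to the smallest replicate total, excluding depth bias.
#' For each feature the squared coefficient of variation CV^2 across
#' replicates is compared to the Poisson expectation CV^2_Poisson = 1/mean
#' through the mean-corrected residual
#' R_mc = log10(CV^2) - log10(CV^2_Poisson); a reference R_mc distribution
#' is generated by drawing, per feature, as many Poisson replicates at the
#' feature's mean. Pure sampling noise gives R_mc centred at 0.
#'
#' @param mat Count matrix, replicates in rows, features in columns.
#' @param seed Integer seed for the subsampling and the Poisson reference.
#' @return List with `records` (data.frame `feature`, `mean_count`, `cv2`,
#'   `cv2_poisson`, `r_mc`; degenerate features carry NA `r_mc`),
#'   `reference` (numeric vector of simulated R_mc values) and `depth`
#'   (equalized total).
#' @export
technical_noise <- function(mat, seed = 1L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("at least two replicates are required")
  set.seed(seed)
  depth <- min(rowSums(mat))
  sub <- t(apply(mat, 1L, function(row) {
    tot <- sum(row)
    if (tot == depth) return(row)
    drawn <- sample.int(tot, depth)
    pool <- rep.int(seq_along(row), row)
    tabulate(pool[drawn], nbins = length(row))
  }))
  means <- colMeans(sub)
  cv2 <- apply(sub, 2L, stats::var) / means^2
  cv2_pois <- 1 / means
  r_mc <- ifelse(means > 0 & cv2 > 0, log10(cv2) - log10(cv2_pois), NA_real_)
  features <- colnames(mat)
  if (is.null(features)) features <- paste0("f", seq_len(ncol(mat)))

  nrep <- nrow(mat)
  ref <- vapply(means[means > 0], function(m) {
    x <- stats::rpois(nrep, m)
    mu <- mean(x)
    v <- stats::var(x)
    if (mu == 0 || v == 0) return(NA_real_)
    log10(v / mu^2) - log10(1 / mu)
  }, numeric(1))
  list(records = data.frame(feature = features, mean_count = means,
                            cv2 = cv2, cv2_poisson = cv2_pois, r_mc = r_mc,
                            stringsAsFactors = FALSE, row.names = NULL),
       reference = unname(ref[!is.na(ref)]),
       depth = depth)
}

#' Poisson sampling-noise envelope for a pair of counts
#'
#' For counts a and b measured at depths `total_a` and `total_b`, the
#' two-sided Poisson quantile envelope at the given confidence is
#' constructed symmetrically: b must lie within the quantile bounds of a
#' Poisson with mean a/total_a * total_b, and a within the bounds implied
#' by b. A pair inside both is compatible with pure sampling noise.
#'
#' @param count_a,count_b Non-negative counts (vectorized).
#' @param total_a,total_b Positive totals (sequencing-determined cells) of
#'   the two samples.
#' @param confidence Envelope confidence in (0, 1). Default 0.999.
#' @return data.frame with the four bounds (`lower_b`, `upper_b` for b
#'   given a; `lower_a`, `upper_a` for a given b) and `within`.
#' @export
sampling_envelope <- function(count_a, count_b, total_a, total_b,
                              confidence = 0.999) {
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (any(c(total_a, total_b) <= 0)) stop("totals must be positive")
  alpha <- 1 - confidence
  lam_b <- count_a / total_a * total_b
  lam_a <- count_b / total_b * total_a
  lower_b <- stats::qpois(alpha / 2, lam_b)
  upper_b <- stats::qpois(1 - alpha / 2, lam_b)
  lower_a <- stats::qpois(alpha / 2, lam_a)
  upper_a <- stats::qpois(1 - alpha / 2, lam_a)
  within <- count_b >= lower_b & count_b <= upper_b &
    count_a >= lower_a & count_a <= upper_a
  data.frame(lower_b = lower_b, upper_b = upper_b,
             lower_a = lower_a, upper_a = upper_a,
             within = within)
}

#' Classify features as differential by the envelope + fold rule
#'
#' A feature is differentially abundant between two samples when its pair
#' of depth-normalized counts falls outside the Poisson sampling envelope
#' AND changes at least `fold_threshold`-fold; differential features are
#' sub-classed at `upper_fold`. The proportion of differential features is
#' reported over detected features (nonzero in either sample).
#'
#' @param count_a,count_b Raw count vectors of the two samples.
#' @param total_a,total_b Totals (defaults: the sums of the vectors).
#' @param fold_threshold Minimum fold change. Default 2.
#' @param upper_fold Sub-classing threshold. Default 10.
#' @param confidence Envelope confidence. Default 0.999.
#' @return List with `table` (per-feature data.frame: normalized counts,
#'   `fold_change`, `within_envelope`, `class` in
#'   noise / differential-2to10 / differential-gt10) and
#'   `proportion_differential`.
#' @export
classify_differential <- function(count_a, count_b,
                                  total_a = sum(count_a),
                                  total_b = sum(count_b),
                                  fold_threshold = 2, upper_fold = 10,
                                  confidence = 0.999) {
  stopifnot(length(count_a) == length(count_b))
  env <- sampling_envelope(count_a, count_b, total_a, total_b, confidence)
  norm_a <- count_a / total_a
  norm_b <- count_b / total_b
  fold <- ifelse(norm_a == 0 & norm_b == 0, NA_real_,
                 pmax(norm_a, norm_b) / pmin(norm_a, norm_b))
  detected <- count_a > 0 | count_b > 0
  differential <- detected & !env$within & !is.na(fold) &
    fold >= fold_threshold
  cls <- rep("noise", length(count_a))
  cls[differential & fold < upper_fold] <- sprintf("differential-%gto%g",
                                                   fold_threshold, upper_fold)
  cls[differential & fold >= upper_fold] <- sprintf("differential-gt%g",
                                                    upper_fold)
  tab <- data.frame(count_a = count_a, count_b = count_b,
                    norm_a = norm_a, norm_b = norm_b,
                    fold_change = fold,
                    within_envelope = env$within,
                    class = cls,
                    stringsAsFactors = FALSE)
  list(table = tab,
       proportion_differential = if (any(detected))
         sum(differential) / sum(detected) else NA_real_)
}

#' Simulate substitution accumulation over PCR cycles
#'
#' Branching-process model of PCR mutagenesis: each cycle every molecule is
#' replicated semiconservatively into two daughters, each of which acquires
#' Binomial(L, rate) new substitutions (each daughter duplex contains one
#' newly synthesized strand). Clones are sampled uniformly from the final
#' pool and their substitution distance to the template is returned; the
#' expected distance is L * rate * n_cycles. Explains why Sanger sequencing
#' of cloned amplicons shows one-to-few substitutions from the true
#' template at typical polymerase error rates.
#'
#' The in-memory pool is capped (default 1e5 molecules) with uniform
#' lineage subsampling once it exceeds the cap.
#'
#' @param template_length Template length L in bases.
#' @param n_cycles Number of PCR cycles.
#' @param rate Per-base per-duplication substitution probability.
#' @param n_clones Number of clones sampled from the final pool.
#' @param seed Integer seed.
#' @param pool_cap Maximum molecules kept in memory. Default 1e5.
#' @return Integer vector of substitution counts per sampled clone.
#' @examples
#' mean(pcr_error_sim(450, 30, 1e-4, 2000, seed = 1)) # ~1.35
#' @export
pcr_error_sim <- function(template_length, n_cycles, rate, n_clones,
                          seed, pool_cap = 1e5) {
  stopifnot(rate >= 0, rate <= 1, template_length >= 1, n_cycles >= 0,
            n_clones >= 1)
  set.seed(seed)
  pool <- 0L # substitution count of the initial template molecule
  for (cyc in seq_len(n_cycles)) {
    n <- length(pool)
    pool <- c(pool + stats::rbinom(n, template_length, rate),
              pool + stats::rbinom(n, template_length, rate))
    if (length(pool) > pool_cap) {
      pool <- pool[sample.int(length(pool), pool_cap)]
    }
  }
  pool[sample.int(length(pool), n_clones, replace = n_clones > length(pool))]
}
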