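# Downstream count statistics: median-of-ratios normalization, Bray-Curtis
# dissimilarity, analytic rarefaction, abundance prefilter. All matrices
# are samples x features (rows = samples), the community-ecology layout.

#' Median-of-ratios size factors
#'
#' For each sample the factor is the median, over features with all-positive
#' counts across samples, of the sample's count divided by the feature's
#' geometric mean. Multiplying one sample's counts by c multiplies its
#' factor by c.
#'
#' @param mat Numeric matrix, samples in rows, features in columns.
#' @return Named numeric vector of per-sample size factors.
#' @examples
#' size_factors(rbind(s1 = c(10, 20), s2 = c(20, 40))) # 0.7071, 1.4142
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  pos <- colSums(mat > 0) == nrow(mat)
  if (!any(pos)) stop("no feature has positive counts in every sample")
  m <- mat[, pos, drop = FALSE]
  log_gm <- colMeans(log(m))
  f <- apply(m, 1L, function(row) exp(stats::median(log(row) - log_gm)))
  stats::setNames(as.numeric(f), rownames(mat))
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' sum |a_i - b_i| / sum (a_i + b_i); 0 for identical profiles, 1 for
#' disjoint supports.
#'
#' @param a,b Non-negative numeric vectors over the same feature set.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(2, 1), c(1, 1)) # 0.2
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  denom <- sum(a + b)
  if (denom == 0) stop("both profiles are all-zero")
  sum(abs(a - b)) / denom
}

#' Expected richness in a subsample (analytic rarefaction)
#'
#' Hypergeometric expectation of the number of features observed when
#' drawing `depth` individuals without replacement from a count vector:
#' E(S) = sum_i (1 - choose(N - N_i, n) / choose(N, n)).
#'
#' @param counts Non-negative integer vector of per-feature counts.
#' @param depth Subsample size, 1 <= depth <= sum(counts).
#' @return Expected number of observed features.
#' @examples
#' rarefied_richness(c(5, 5), 2) # 1.5556
#' @export
rarefied_richness <- function(counts, depth) {
  if (any(counts < 0)) stop("counts must be non-negative")
  N <- sum(counts)
  if (depth > N) stop("depth exceeds the total count")
  if (depth < 1) stop("depth must be at least 1")
  counts <- counts[counts > 0]
  # log-scale for numeric stability; features with N - N_i < depth are
  # certain to appear.
  p_absent <- ifelse(N - counts < depth, 0,
                     exp(lchoose(N - counts, depth) - lchoose(N, depth)))
  sum(1 - p_absent)
}

#' Filter features by a minimum count in a minimum number of samples
#'
#' Keeps features with raw counts of at least `min_count` in at least
#' `min_samples` samples, the standard prefilter before differential
#' abundance testing. When `groups` is given the rule must hold within
#' every group.
#'
#' @param mat Count matrix, samples in rows.
#' @param min_count Minimum raw count. Default 5.
#' @param min_samples Minimum number of qualifying samples. Default 3.
#' @param groups Optional factor over rows; the rule is applied per group.
#' @return The matrix restricted to surviving features (columns).
#' @export
prefilter_counts <- function(mat, min_count = 5L, min_samples = 3L,
                             groups = NULL) {
  mat <- as.matrix(mat)
  rule <- function(m) colSums(m >= min_count) >= min_samples
  keep <- if (is.null(groups)) {
    rule(mat)
  } else {
    stopifnot(length(groups) == nrow(mat))
    Reduce(`&`, lapply(split(seq_len(nrow(mat)), groups),
                       function(i) rule(mat[i, , drop = FALSE])))
  }
  mat[, keep, drop = FALSE]
}
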