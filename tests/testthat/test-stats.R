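test_that("size factors reproduce median-of-ratios identities", {
  m <- rbind(s1 = c(10, 30, 50), s2 = c(10, 30, 50))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- rbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
  f <- size_factors(m2)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(round(unname(f), 4), c(0.7071, 1.4142))
  # scaling one sample by c scales its factor relative to the others by c
  # (the geometric-mean denominator reabsorbs c^(1/n))
  m3 <- m2
  m3["s1", ] <- m3["s1", ] * 5
  f3 <- size_factors(m3)
  expect_equal(f3[["s1"]] / f3[["s2"]], 5 * f[["s1"]] / f[["s2"]],
               tolerance = 1e-12)
  # feature permutation leaves factors unchanged
  set.seed(81)
  m4 <- matrix(rpois(60, 40) + 1, nrow = 3,
               dimnames = list(paste0("s", 1:3), NULL))
  expect_equal(size_factors(m4), size_factors(m4[, sample(ncol(m4))]))
  expect_error(size_factors(rbind(c(0, 5), c(3, 0))), "positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(82)
  m <- matrix(rpois(200, 60) + 1, nrow = 4,
              dimnames = list(paste0("s", 1:4), NULL))
  ref <- DESeq2::estimateSizeFactorsForMatrix(t(m))
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-8)
})

test_that("Bray-Curtis dissimilarity matches its definition and vegan", {
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_equal(bray_curtis(c(3, 0, 2), c(3, 0, 2)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(83)
  for (i in 1:5) {
    a <- rpois(20, 5); b <- rpois(20, 5)
    if (sum(a + b) == 0) next
    d <- bray_curtis(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(b, a))
  }
  skip_if_not_installed("vegan")
  a <- c(12, 0, 3, 9, 1); b <- c(4, 7, 3, 0, 2)
  expect_equal(bray_curtis(a, b),
               as.numeric(vegan::vegdist(rbind(a, b), method = "bray")),
               tolerance = 1e-12)
})

test_that("analytic rarefaction matches closed form, Monte-Carlo and vegan", {
  expect_equal(rarefied_richness(c(5, 5), 2),
               2 * (1 - choose(5, 2) / choose(10, 2)))
  expect_equal(round(rarefied_richness(c(5, 5), 2), 4), 1.5556)
  counts <- c(40, 10, 3, 1, 0, 25)
  expect_equal(rarefied_richness(counts, sum(counts)), sum(counts > 0))
  expect_equal(rarefied_richness(counts, 1), 1)
  expect_error(rarefied_richness(counts, sum(counts) + 1), "exceeds")
  # Monte-Carlo subsampling oracle
  set.seed(84)
  depth <- 20
  pool <- rep.int(seq_along(counts), counts)
  draws <- replicate(1e4, length(unique(sample(pool, depth))))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - rarefied_richness(counts, depth)), 3 * se)
  skip_if_not_installed("vegan")
  expect_equal(rarefied_richness(counts, depth),
               as.numeric(vegan::rarefy(counts, depth)), tolerance = 1e-8)
})

test_that("prefilter keeps features with enough well-covered samples", {
  m <- rbind(s1 = c(5, 0, 2, 9, 0, 5),
             s2 = c(5, 0, 3, 9, 1, 4),
             s3 = c(5, 0, 7, 9, 2, 6),
             s4 = c(0, 0, 1, 9, 3, 7))
  colnames(m) <- paste0("f", 1:6)
  out <- prefilter_counts(m, min_count = 5, min_samples = 3)
  # hand evaluation: f1 has 5,5,5,0 -> kept; f2 all zero -> dropped;
  # f3 has one >=5 -> dropped; f4 all 9 -> kept; f5 none >=5 -> dropped;
  # f6 has 5,6,7 -> kept
  expect_equal(colnames(out), c("f1", "f4", "f6"))
  expect_equal(unname(out[1, ]), c(5, 9, 5))
  grp <- factor(c("g1", "g1", "g2", "g2"))
  out2 <- prefilter_counts(m, min_count = 5, min_samples = 1, groups = grp)
  expect_equal(ncol(out2), 3) # f6: 5,4 | 6,7 -> qualifies in both groups
})

test_that("technical noise recovers the CV2 arithmetic and Poisson residual", {
  # equal replicate depths: subsampling is the identity
  m <- rbind(r1 = c(90, 110), r2 = c(100, 100), r3 = c(110, 90))
  out <- technical_noise(m, seed = 1)
  expect_equal(out$depth, 200)
  expect_equal(out$records$cv2[1], 100 / 100^2)
  expect_equal(out$records$cv2_poisson[1], 1 / 100)
  expect_equal(out$records$r_mc[1], 0)
  # identical replicates: CV2 = 0, residual undefined
  m2 <- rbind(r1 = c(50, 50), r2 = c(50, 50))
  out2 <- technical_noise(m2, seed = 2)
  expect_true(all(is.na(out2$records$r_mc)))
  expect_error(technical_noise(m[1, , drop = FALSE]), "two replicates")
})

test_that("replicate subsampling equalizes depths", {
  set.seed(85)
  m <- rbind(r1 = rpois(50, 30), r2 = rpois(50, 36), r3 = rpois(50, 33))
  out <- technical_noise(m, seed = 3)
  expect_equal(out$depth, min(rowSums(m)))
  # mean counts reflect the equalized depth, not the raw one
  expect_lt(sum(out$records$mean_count) * nrow(m),
            sum(m) + 1e-9)
})

test_that("sampling envelopes contain equal counts and exclude large shifts", {
  e1 <- sampling_envelope(100, 100, 1000, 1000)
  expect_true(e1$within)
  e2 <- sampling_envelope(100, 300, 1000, 1000)
  expect_false(e2$within)
  # envelope widens monotonically with confidence
  widths <- vapply(c(0.9, 0.99, 0.999, 0.9999), function(cf) {
    e <- sampling_envelope(100, 100, 1000, 1000, confidence = cf)
    e$upper_b - e$lower_b
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
  expect_error(sampling_envelope(10, 10, 100, 100, confidence = 1.2),
               "confidence")
  expect_error(sampling_envelope(10, 10, 0, 100), "positive")
})

test_that("the differential rule requires both envelope breach and fold change", {
  # inside the envelope with a 3-fold ratio: noise
  r1 <- classify_differential(1, 3, 1000, 1000)
  expect_equal(r1$table$class, "noise")
  # outside the envelope but below 2-fold: noise
  r2 <- classify_differential(10000, 15000, 1e5, 1e5)
  expect_false(r2$table$within_envelope)
  expect_equal(r2$table$class, "noise")
  # outside and 2-10 fold / >10 fold sub-classing
  r3 <- classify_differential(c(100, 20), c(500, 450), 1e4, 1e4)
  expect_equal(r3$table$class,
               c("differential-2to10", "differential-gt10"))
  expect_equal(r3$proportion_differential, 1)
})

test_that("PCR error accumulation matches the lineage expectation", {
  d0 <- pcr_error_sim(450, 25, 0, 500, seed = 1)
  expect_true(all(d0 == 0))
  d <- pcr_error_sim(450, 30, 1e-4, 5000, seed = 2)
  # expected substitutions per clone: L * rate * cycles = 1.35
  expect_lt(abs(mean(d) - 1.35), 3 * stats::sd(d) / sqrt(length(d)) + 0.05)
  # fraction of error-free clones decreases with the error rate
  f0 <- vapply(c(1e-5, 1e-4, 1e-3), function(r) {
    mean(pcr_error_sim(450, 30, r, 2000, seed = 3) == 0)
  }, numeric(1))
  expect_true(all(diff(f0) < 0))
})
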