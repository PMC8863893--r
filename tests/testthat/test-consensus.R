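test_that("perfect read pairs merge back to the template", {
  tpl <- random_dna(1, 450, seed = 51)
  trip <- perfect_triplet(tpl, barcode = make_barcodes(1, seed = 52))
  m <- merge_pair(trip$i1, trip$qi1, trip$r2, trip$q2)
  expect_equal(m$sequence, tpl)
  expect_equal(m$overlap, 140) # 295 + 295 - 450
  expect_equal(m$mismatches, 0)
})

test_that("overlap disagreements follow the higher-quality read", {
  tpl <- random_dna(1, 60, seed = 53)
  i1 <- substr(tpl, 1, 40)
  r2 <- revcomp_chr(substr(tpl, 21, 60))
  # mismatch inside the 20-base overlap, carried by the forward read
  bad_i1 <- i1
  p <- 30L
  substr(bad_i1, p, p) <- if (substr(bad_i1, p, p) == "A") "C" else "A"
  q20 <- strrep(rawToChar(as.raw(20 + 33)), 40)
  q40 <- strrep(rawToChar(as.raw(40 + 33)), 40)
  # forward low quality: reverse read wins, template restored
  m1 <- merge_pair(bad_i1, q20, r2, q40, min_overlap = 10)
  expect_equal(m1$sequence, tpl)
  expect_equal(m1$mismatches, 1)
  # forward high quality: the erroneous base survives
  m2 <- merge_pair(bad_i1, q40, r2, q20, min_overlap = 10)
  expect_equal(substr(m2$sequence, p, p), substr(bad_i1, p, p))
  # agreeing bases keep the maximum quality
  m3 <- merge_pair(i1, q20, r2, q40, min_overlap = 10)
  expect_equal(substr(m3$quality, 25, 25), rawToChar(as.raw(40 + 33)))
  expect_equal(substr(m3$quality, 5, 5), rawToChar(as.raw(20 + 33)))
})

test_that("pairs without an admissible overlap are rejected", {
  a <- random_dna(1, 100, seed = 54)
  b <- random_dna(1, 100, seed = 55) # unrelated: no true overlap
  q <- strrep("I", 100)
  expect_null(merge_pair(a, q, b, q, min_overlap = 20,
                         max_overlap_mismatch_frac = 0.05))
})

test_that("within-barcode clustering separates true variants from errors", {
  base <- random_dna(1, 100, seed = 56)
  err <- base
  substr(err, 10, 10) <- if (substr(err, 10, 10) == "G") "T" else "G"
  grp <- cluster_within_barcode(c(rep(base, 10), err), max_intra_distance = 5)
  expect_equal(length(unique(grp)), 1)

  far <- base
  for (p in c(5L, 15L, 25L, 35L, 45L, 55L, 65L, 75L)) {
    substr(far, p, p) <- if (substr(far, p, p) == "A") "C" else "A"
  }
  grp2 <- cluster_within_barcode(c(rep(base, 5), rep(far, 5)),
                                 max_intra_distance = 5)
  expect_equal(length(unique(grp2)), 2)

  expect_equal(cluster_within_barcode(base), 1L)
  # exact-type grouping (default distance 0) keeps one-base variants apart
  grp3 <- cluster_within_barcode(c(rep(base, 6), rep(err, 5)))
  expect_equal(length(unique(grp3)), 2)
})

test_that("RepSeq calling weights votes by read count and quality", {
  q <- function(ch, n) strrep(ch, n)
  # 5 reads ACGT at Q30 vs 1 read ACGA at Q20: count wins
  r <- call_repseq(c(rep("ACGT", 5), "ACGA"),
                   c(rep(q("?", 4), 5), q("5", 4)))
  expect_equal(r$sequence, "ACGT")
  expect_equal(r$read_support, 6)
  # single read is its own RepSeq
  r1 <- call_repseq("ACGT", q("I", 4))
  expect_equal(r1$sequence, "ACGT")
  # equal counts: the higher-quality pair wins the contested position
  hi <- rawToChar(as.raw(40 + 33)) # weight 0.9999
  lo <- rawToChar(as.raw(10 + 33)) # weight 0.9
  r2 <- call_repseq(c("ACGT", "ACGT", "ACGA", "ACGA"),
                    c(q(hi, 4), q(hi, 4), q(lo, 4), q(lo, 4)))
  expect_equal(substr(r2$sequence, 4, 4), "T")
})

test_that("error filtering removes low-support RepSeqs and rare sequences", {
  reps <- data.frame(
    barcode_cluster_id = c("b1", "b1", "b2", "b3", "b3"),
    sequence = c("AAAA", "CCCC", "AAAA", "AAAA", "GGGG"),
    read_support = c(50L, 1L, 40L, 30L, 10L),
    stringsAsFactors = FALSE)
  out <- filter_errors(reps, min_reads_per_repseq = 3, min_cell_support = 2,
                       min_minor_fraction = 0.1)
  # CCCC: 1 read < 0.1 * 50 -> dropped; GGGG: one barcode only -> dropped
  expect_equal(out$bar_sequences$sequence, "AAAA")
  expect_equal(out$bar_sequences$n_barcodes, 3L)
  expect_equal(nrow(out$assignment), 3)

  # all thresholds disabled: identity pass-through
  out2 <- filter_errors(reps, min_reads_per_repseq = 0, min_cell_support = 1,
                        min_minor_fraction = 0)
  expect_setequal(out2$bar_sequences$sequence,
                  c("AAAA", "CCCC", "GGGG"))
  expect_equal(nrow(out2$assignment), nrow(reps))
  # bar ids ordered by barcode support then sequence
  expect_equal(out2$bar_sequences$bar_id[1], "Bar0001")
  expect_equal(out2$bar_sequences$sequence[1], "AAAA")

  expect_warning(empty <- filter_errors(reps[0, , drop = FALSE]), "no RepSeqs")
  expect_equal(nrow(empty$bar_sequences), 0)
})

test_that("no surviving Bar sequence lacks barcode support", {
  set.seed(57)
  reps <- data.frame(
    barcode_cluster_id = sample(paste0("b", 1:20), 60, replace = TRUE),
    sequence = sample(random_dna(6, 30), 60, replace = TRUE),
    read_support = sample(1:40, 60, replace = TRUE),
    stringsAsFactors = FALSE)
  reps <- unique(reps)
  out <- filter_errors(reps)
  if (nrow(out$bar_sequences)) {
    per_bar <- table(out$assignment$bar_id)
    expect_true(all(out$bar_sequences$bar_id %in% names(per_bar)))
    expect_equal(as.integer(per_bar[out$bar_sequences$bar_id]),
                 out$bar_sequences$n_barcodes)
  }
})
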