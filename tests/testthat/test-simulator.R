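test_that("barcodes are 24 random bases plus a designed 6-base tag", {
  bc <- make_barcodes(4, seed = 1)
  expect_length(bc, 4)
  expect_true(all(nchar(bc) == 30))
  expect_setequal(substr(bc, 25, 30), barcode_tags())
  expect_identical(make_barcodes(50, seed = 9), make_barcodes(50, seed = 9))
  expect_false(identical(make_barcodes(50, seed = 9),
                         make_barcodes(50, seed = 10)))
  big <- make_barcodes(1e5, seed = 3)
  expect_equal(attr(big, "collision_expectation"),
               choose(1e5, 2) / 4^24, tolerance = 1e-12)
  expect_lt(attr(big, "collision_expectation"), 2e-5)
})

test_that("droplet occupancy follows the Poisson draw", {
  comm <- community_spec(list(
    strain_spec("A", random_dna(1, 450, seed = 5), 1L, concentration = 1)))
  # single strain at lambda 0.2 over 1e5 droplets
  enc <- encapsulation_spec(emulsion_volume = 1e5 * droplet_volume(120) / 1e3,
                            n_barcodes = 0)
  comm$strains[[1]]$concentration <- 0.2 * 1e5 / enc$emulsion_volume
  truth <- simulate_droplets(comm, enc, seed = 21)
  occupied <- length(unique(truth$cells$droplet))
  p_occ <- 1 - exp(-0.2)
  se <- sqrt(p_occ * (1 - p_occ) * truth$n_droplets)
  expect_lt(abs(occupied - p_occ * truth$n_droplets), 3 * se)
  # singleton fraction among occupied droplets
  per_drop <- table(truth$cells$droplet)
  phat <- mean(per_drop == 1)
  se1 <- sqrt(phat * (1 - phat) / length(per_drop))
  expect_lt(abs(phat - singleton_fraction(0.2)), 3 * se1)
  # conservation: strain totals match the assignment table
  expect_equal(sum(truth$strain_counts), nrow(truth$cells))
})

test_that("zero concentration yields zero cells and empty communities fail", {
  comm <- community_spec(list(
    strain_spec("A", random_dna(1, 450, seed = 6), 1L, concentration = 0)))
  truth <- simulate_droplets(comm, small_encapsulation(1000), seed = 2)
  expect_equal(nrow(truth$cells), 0)
  expect_error(community_spec(list()), "length")
})

test_that("strain shares follow concentrations", {
  seqs <- random_dna(2, 450, seed = 7)
  enc <- small_encapsulation(20000)
  conc <- 2000 / enc$emulsion_volume / 2
  comm <- community_spec(list(strain_spec("A", seqs[1], 1L, conc),
                              strain_spec("B", seqs[2], 1L, conc)))
  truth <- simulate_droplets(comm, enc, seed = 8)
  n <- nrow(truth$cells)
  share <- truth$strain_counts[["A"]] / n
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / n))
})

test_that("error-free reads reconstruct their templates exactly", {
  tpl <- random_dna(1, 450, seed = 11)
  comm <- community_spec(list(strain_spec("A", tpl, 1L, 50)))
  enc <- small_encapsulation(400)
  truth <- simulate_droplets(comm, enc, seed = 12)
  reads <- simulate_reads(truth, comm, error = error_model(substitution_rate = 0),
                          rpm = reads_per_molecule("constant", mean = 2),
                          seed = 13)
  expect_gt(nrow(reads), 0)
  expect_true(all(reads$i1 == substr(tpl, 1, 295)))
  expect_true(all(reads$r2 == revcomp_chr(substr(tpl, 156, 450))))
  origin <- attr(reads, "origin")
  expect_equal(nrow(origin), nrow(reads))
  # every read traces to a barcode of its droplet
  key_reads <- paste(origin$droplet, origin$barcode_id)
  key_truth <- paste(truth$barcodes$droplet, truth$barcodes$barcode_id)
  expect_true(all(key_reads %in% key_truth))
})

test_that("substitution rate sets the per-read error load and qualities", {
  tpl <- random_dna(1, 450, seed = 14)
  comm <- community_spec(list(strain_spec("A", tpl, 1L, 200)))
  truth <- simulate_droplets(comm, small_encapsulation(2000), seed = 15)
  reads <- simulate_reads(truth, comm,
                          error = error_model(substitution_rate = 0.001),
                          rpm = reads_per_molecule("constant", mean = 3),
                          seed = 16)
  i1_ref <- substr(tpl, 1, 295)
  nerr <- vapply(reads$i1, function(s) {
    sum(charToRaw(s) != charToRaw(i1_ref))
  }, numeric(1), USE.NAMES = FALSE)
  n <- length(nerr)
  expect_lt(abs(mean(nerr) - 0.295), 3 * sqrt(0.295 / n))
  # erroneous bases are flagged at the error quality
  qerr <- rawToChar(as.raw(12 + 33))
  has_err <- which(nerr > 0)[1]
  pos <- which(charToRaw(reads$i1[has_err]) != charToRaw(i1_ref))[1]
  expect_equal(substr(reads$qi1[has_err], pos, pos), qerr)
})

test_that("multi-variant strains emit all variants under one barcode", {
  v <- random_dna(2, 450, seed = 17)
  comm <- community_spec(list(strain_spec("A", v, c(1L, 1L), 30)))
  truth <- simulate_droplets(comm, small_encapsulation(500), seed = 18)
  reads <- simulate_reads(truth, comm, error = error_model(substitution_rate = 0),
                          rpm = reads_per_molecule("constant", mean = 2),
                          seed = 19)
  origin <- attr(reads, "origin")
  per_bc <- split(origin$template_id, origin$barcode_id)
  expect_true(all(vapply(per_bc, function(x) {
    setequal(unique(x), c("Av1", "Av2"))
  }, logical(1))))
})

test_that("too-short variants are rejected", {
  comm <- community_spec(list(strain_spec("A", random_dna(1, 200, seed = 20),
                                          1L, 10)))
  truth <- simulate_droplets(comm, small_encapsulation(200), seed = 21)
  expect_error(simulate_reads(truth, comm, seed = 22), "at least 295")
})

test_that("FASTQ round trip preserves sequences and qualities", {
  tpl <- random_dna(1, 450, seed = 23)
  comm <- community_spec(list(strain_spec("A", tpl, 1L, 100)))
  truth <- simulate_droplets(comm, small_encapsulation(1000), seed = 24)
  reads <- simulate_reads(truth, comm, seed = 25)
  dir <- withr::local_tempdir()
  paths <- write_run(reads, dir, prefix = "rt", truth = truth)
  back <- parse_run(paths$r1, paths$i1, paths$r2)
  expect_equal(nrow(back), nrow(reads))
  expect_identical(back$i1, reads$i1)
  expect_identical(back$qi1, reads$qi1)
  expect_identical(back$r1, reads$r1)
  expect_identical(back$r2, reads$r2)
  expect_identical(back$q2, reads$q2)
  expect_true(file.exists(paths$truth_strain_counts))
})

test_that("an empty run writes three valid empty FASTQ files", {
  empty <- data.frame(read_id = character(0), r1 = character(0),
                      q1 = character(0), i1 = character(0),
                      qi1 = character(0), r2 = character(0),
                      q2 = character(0), stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_run(empty, dir, prefix = "empty")
  expect_true(all(file.exists(unlist(paths))))
  back <- parse_run(paths$r1, paths$i1, paths$r2)
  expect_equal(nrow(back), 0)
})
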