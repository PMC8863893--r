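# Synthetic barcoded droplet-sequencing runs with full ground truth.
# Reads are emitted only from droplets holding both a barcode and at least
# one 16S template, mirroring the single-step in-droplet amplification.

.BASES <- c("A", "C", "G", "T")

# The four designed 6-base fixed tags appended to the 24 random barcode bases.
.BARCODE_TAGS <- c("ATCACG", "CGATGT", "TTAGGC", "TGACCA")

#' Fixed 6-base tags used in cellular barcodes
#'
#' Barcodes are 30 nt: 24 random bases followed by one of four designed
#' 6-base tags.
#'
#' @return Character vector of the four tags.
#' @export
barcode_tags <- function() .BARCODE_TAGS

.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.phred_char <- function(q) rawToChar(as.raw(q + 33L))

#' Generate cellular barcode sequences
#'
#' Each barcode is 24 uniformly random bases followed by one of the four
#' fixed 6-base tags, cycled so the tags are used evenly. Distinctness is
#' not enforced; the expected number of colliding random-portion pairs
#' (choose(n,2) / 4^24) is attached as attribute `collision_expectation`.
#'
#' @param n Number of barcodes (>= 1).
#' @param seed Integer seed; identical seeds give identical barcodes.
#' @return Character vector of 30 nt barcodes.
#' @examples
#' make_barcodes(4, seed = 1)
#' @export
make_barcodes <- function(n, seed) {
  stopifnot(length(n) == 1L, n >= 1)
  set.seed(seed)
  random <- .random_dna(n, 24L)
  tags <- .BARCODE_TAGS[((seq_len(n) - 1L) %% 4L) + 1L]
  out <- paste0(random, tags)
  attr(out, "collision_expectation") <- choose(n, 2) / 4^24
  out
}

#' Strain specification for the simulator
#'
#' A strain carries one to a few distinct 16S V3-V4 variant sequences, each
#' with a per-genome copy number, and a concentration in cells per
#' microlitre of the emulsified suspension.
#'
#' @param strain_id Label.
#' @param variants Character vector of distinct variant sequences
#'   (DNA, ~450 nt each).
#' @param copies Integer copy number per genome for each variant (>= 1).
#' @param concentration Cells per microlitre (>= 0).
#' @return An object of class `strain_spec`.
#' @export
strain_spec <- function(strain_id, variants, copies = rep(1L, length(variants)),
                        concentration) {
  stopifnot(length(variants) >= 1L, length(copies) == length(variants),
            all(copies >= 1), concentration >= 0)
  if (anyDuplicated(variants)) stop("variant sequences must be distinct within a strain")
  structure(list(strain_id = as.character(strain_id),
                 variants = toupper(as.character(variants)),
                 copies = as.integer(copies),
                 concentration = concentration),
            class = "strain_spec")
}

#' Community specification for the simulator
#'
#' @param strains List of [strain_spec()] objects.
#' @param ecdna Optional data.frame with columns `sequence` and
#'   `concentration` (fragments per microlitre) describing cell-free 16S
#'   fragments.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(strains, ecdna = NULL) {
  stopifnot(length(strains) >= 1L,
            all(vapply(strains, inherits, logical(1), "strain_spec")))
  ids <- vapply(strains, `[[`, character(1), "strain_id")
  if (anyDuplicated(ids)) stop("strain ids must be unique")
  if (!is.null(ecdna)) {
    stopifnot(is.data.frame(ecdna), all(c("sequence", "concentration") %in% names(ecdna)),
              all(ecdna$concentration >= 0))
  }
  structure(list(strains = strains, ecdna = ecdna), class = "community_spec")
}

#' Variant table of a community
#'
#' @param community A [community_spec()].
#' @return data.frame with `strain_id`, `variant_id`, `sequence`, `copies`.
#' @export
community_variants <- function(community) {
  stopifnot(inherits(community, "community_spec"))
  rows <- lapply(community$strains, function(s) {
    data.frame(strain_id = s$strain_id,
               variant_id = paste0(s$strain_id, "v", seq_along(s$variants)),
               sequence = s$variants,
               copies = s$copies,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sequencing error model
#'
#' Substitution-only error model: each base is substituted independently
#' with `substitution_rate`; substituted bases are reported at
#' `quality_error`, all others at `quality_correct` (Phred). Chimeras, when
#' enabled, recombine two templates of the same droplet at a uniform
#' breakpoint; amplification inside droplets confines chimerism to
#' within-droplet templates.
#'
#' @param substitution_rate Per-base substitution probability in `[0, 1]`.
#' @param quality_correct,quality_error Phred scores in `[2, 41]`.
#' @param chimera_rate Per-read probability of a within-droplet chimera.
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.001, quality_correct = 37L,
                        quality_error = 12L, chimera_rate = 0) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            quality_correct >= 2, quality_correct <= 41,
            quality_error >= 2, quality_error <= 41)
  structure(list(substitution_rate = substitution_rate,
                 quality_correct = as.integer(quality_correct),
                 quality_error = as.integer(quality_error),
                 chimera_rate = chimera_rate),
            class = "error_model")
}

#' Reads-per-molecule distribution
#'
#' Amplification is not simulated cycle by cycle for read emission; the
#' pipeline only consumes read multiplicities, so the number of read
#' triplets per (barcode, template copy) is drawn from a configurable
#' distribution: negative binomial (`mean`, `size`), Poisson (`mean`) or a
#' constant.
#'
#' @param dist `"nbinom"`, `"poisson"` or `"constant"`.
#' @param mean Mean reads per template molecule.
#' @param size Negative-binomial dispersion parameter (ignored otherwise).
#' @return An object of class `reads_per_molecule`.
#' @export
reads_per_molecule <- function(dist = c("nbinom", "poisson", "constant"),
                               mean = 12, size = 10) {
  dist <- match.arg(dist)
  stopifnot(mean >= 0, size > 0)
  structure(list(dist = dist, mean = mean, size = size),
            class = "reads_per_molecule")
}

.draw_rpm <- function(rpm, n) {
  if (n == 0L) return(integer(0))
  switch(rpm$dist,
         nbinom = stats::rnbinom(n, mu = rpm$mean, size = rpm$size),
         poisson = stats::rpois(n, rpm$mean),
         constant = rep(as.integer(round(rpm$mean)), n))
}

#' Simulate Poisson encapsulation of a community into droplets
#'
#' Barcodes, cells of each strain, and ecDNA fragments are assigned to
#' droplets by independent Poisson draws. Barcode lambda comes from
#' `encaps$n_barcodes`; each strain's lambda from its concentration times
#' the emulsion volume. The returned ground truth records every droplet
#' assignment and the per-strain totals.
#'
#' @param community A [community_spec()].
#' @param encaps An [encapsulation_spec()].
#' @param seed Integer seed.
#' @return An object of class `ground_truth`: droplet count, lambdas,
#'   `barcodes`/`cells`/`ecdna` assignment tables and `strain_counts`.
#' @export
simulate_droplets <- function(community, encaps, seed) {
  stopifnot(inherits(community, "community_spec"),
            inherits(encaps, "encapsulation_spec"))
  if (length(community$strains) == 0L) stop("community is empty")
  set.seed(seed)
  nd <- as.integer(round(n_droplets(encaps)))
  if (nd <= 0L) stop("encapsulation spec yields no droplets")

  lam_bc <- encaps$n_barcodes / nd
  k_bc <- stats::rpois(nd, lam_bc)
  n_bc <- sum(k_bc)
  bc_seqs <- if (n_bc > 0) make_barcodes(n_bc, seed = seed + 1L) else character(0)
  barcodes <- data.frame(droplet = rep.int(seq_len(nd), k_bc),
                         barcode_id = seq_len(n_bc),
                         sequence = as.character(bc_seqs),
                         stringsAsFactors = FALSE)

  strain_ids <- vapply(community$strains, `[[`, character(1), "strain_id")
  conc <- vapply(community$strains, `[[`, numeric(1), "concentration")
  lam_strain <- conc * encaps$emulsion_volume / nd
  cells_list <- lapply(seq_along(strain_ids), function(i) {
    k <- stats::rpois(nd, lam_strain[i])
    drops <- rep.int(seq_len(nd), k)
    data.frame(droplet = drops,
               strain_id = rep(strain_ids[i], length(drops)),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, cells_list)
  if (nrow(cells)) {
    cells <- cells[order(cells$droplet, cells$strain_id), , drop = FALSE]
    cells$cell_id <- seq_len(nrow(cells))
    rownames(cells) <- NULL
  } else {
    cells$cell_id <- integer(0)
  }

  ecdna <- data.frame(droplet = integer(0), species_id = character(0),
                      fragment_id = integer(0), stringsAsFactors = FALSE)
  if (!is.null(community$ecdna) && nrow(community$ecdna)) {
    lam_frag <- community$ecdna$concentration * encaps$emulsion_volume / nd
    frag_list <- lapply(seq_len(nrow(community$ecdna)), function(i) {
      k <- stats::rpois(nd, lam_frag[i])
      drops <- rep.int(seq_len(nd), k)
      data.frame(droplet = drops,
                 species_id = rep(paste0("F", i), length(drops)),
                 stringsAsFactors = FALSE)
    })
    ecdna <- do.call(rbind, frag_list)
    if (nrow(ecdna)) {
      ecdna <- ecdna[order(ecdna$droplet, ecdna$species_id), , drop = FALSE]
      ecdna$fragment_id <- seq_len(nrow(ecdna))
      rownames(ecdna) <- NULL
    } else {
      ecdna$fragment_id <- integer(0)
    }
  }

  strain_counts <- stats::setNames(
    vapply(strain_ids, function(s) sum(cells$strain_id == s), numeric(1)),
    strain_ids)

  structure(list(n_droplets = nd,
                 lambda_barcode = lam_bc,
                 lambda_strain = stats::setNames(lam_strain, strain_ids),
                 barcodes = barcodes,
                 cells = cells,
                 ecdna = ecdna,
                 strain_counts = strain_counts,
                 encaps = encaps,
                 seed = seed),
            class = "ground_truth")
}

#' Countable ground-truth cell totals per strain
#'
#' The pipeline can only count cells that share a droplet with at least one
#' barcode, and a droplet carrying several barcodes yields one barcode
#' cluster per barcode, each reporting every cOTU present once. The
#' countable truth for a strain is therefore the sum over droplets of
#' (number of barcodes in the droplet) x (strain present in the droplet).
#' The same applies per ecDNA species in fragment mode.
#'
#' @param truth A [simulate_droplets()] ground truth.
#' @return List with `cells` and `fragments`, named numeric vectors.
#' @export
expected_detected_counts <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  bc_per_drop <- tabulate(truth$barcodes$droplet, nbins = truth$n_droplets)
  count_for <- function(df, key) {
    if (!nrow(df)) return(stats::setNames(numeric(0), character(0)))
    present <- unique(df[, c("droplet", key)])
    agg <- tapply(bc_per_drop[present$droplet], present[[key]], sum)
    stats::setNames(as.numeric(agg), names(agg))
  }
  list(cells = count_for(truth$cells, "strain_id"),
       fragments = count_for(truth$ecdna, "species_id"))
}

# Apply iid per-base substitutions to equal-length sequences; returns
# list(seq, qual) with erroneous bases at quality_error.
.apply_substitutions <- function(seqs, len, error) {
  n <- length(seqs)
  qual_ok <- strrep(.phred_char(error$quality_correct), len)
  quals <- rep(qual_ok, n)
  if (n == 0L || error$substitution_rate == 0) {
    return(list(seq = seqs, qual = quals))
  }
  k <- stats::rbinom(n, len, error$substitution_rate)
  hit <- which(k > 0L)
  qe <- .phred_char(error$quality_error)
  for (i in hit) {
    pos <- sample.int(len, k[i])
    s <- seqs[i]
    q <- quals[i]
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(.BASES, old), 1L)
      substr(q, p, p) <- qe
    }
    seqs[i] <- s
    quals[i] <- q
  }
  list(seq = seqs, qual = quals)
}

#' Simulate read triplets from an encapsulated run
#'
#' Every droplet holding at least one barcode and at least one 16S template
#' (a cell's variant or an ecDNA fragment) emits reads: for each
#' (barcode, template) pair, each gene copy contributes a number of read
#' triplets drawn from `rpm`. R1 carries the 30 nt barcode, I1 the first
#' 295 nt of the template and R2 the reverse complement of its last 295 nt;
#' substitutions are applied independently per base. In multi-barcode
#' droplets every template emits under every barcode (the physical mixing
#' behind the uniform count-inflation factor).
#'
#' @param truth Ground truth from [simulate_droplets()].
#' @param community The [community_spec()] used for the truth.
#' @param error An [error_model()].
#' @param rpm A [reads_per_molecule()] distribution.
#' @param seed Integer seed.
#' @return data.frame of read triplets (`read_id`, `r1`, `q1`, `i1`, `qi1`,
#'   `r2`, `q2`) with the per-read origin (droplet, barcode, template) in
#'   attribute `origin`.
#' @export
simulate_reads <- function(truth, community, error = error_model(),
                           rpm = reads_per_molecule(), seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(community, "community_spec"))
  set.seed(seed)
  read_len <- 295L

  variants <- community_variants(community)
  tlen <- nchar(variants$sequence)
  if (any(tlen < read_len)) {
    stop("variant sequences must be at least ", read_len, " nt")
  }
  if (any(tlen > 2L * read_len - 30L)) {
    stop("variant sequences longer than ", 2L * read_len - 30L,
         " nt leave no usable read overlap")
  }

  # Template molecules per droplet: one row per (droplet, template, copies).
  mols <- data.frame(droplet = integer(0), template_id = character(0),
                     sequence = character(0), copies = integer(0),
                     stringsAsFactors = FALSE)
  if (nrow(truth$cells)) {
    cv <- merge(truth$cells, variants, by = "strain_id")
    mols <- rbind(mols, data.frame(droplet = cv$droplet,
                                   template_id = cv$variant_id,
                                   sequence = cv$sequence,
                                   copies = cv$copies,
                                   stringsAsFactors = FALSE))
  }
  if (nrow(truth$ecdna)) {
    idx <- as.integer(sub("^F", "", truth$ecdna$species_id))
    mols <- rbind(mols, data.frame(droplet = truth$ecdna$droplet,
                                   template_id = truth$ecdna$species_id,
                                   sequence = toupper(community$ecdna$sequence[idx]),
                                   copies = 1L,
                                   stringsAsFactors = FALSE))
  }

  empty <- data.frame(read_id = character(0), r1 = character(0),
                      q1 = character(0), i1 = character(0),
                      qi1 = character(0), r2 = character(0),
                      q2 = character(0), stringsAsFactors = FALSE)
  if (!nrow(mols) || !nrow(truth$barcodes)) {
    attr(empty, "origin") <- data.frame(droplet = integer(0),
                                        barcode_id = integer(0),
                                        template_id = character(0))
    return(empty)
  }

  pairs <- merge(mols, truth$barcodes, by = "droplet")
  if (!nrow(pairs)) {
    attr(empty, "origin") <- data.frame(droplet = integer(0),
                                        barcode_id = integer(0),
                                        template_id = character(0))
    return(empty)
  }
  # Reads per pair: sum of one draw per gene copy.
  per_copy <- rep.int(seq_len(nrow(pairs)), pairs$copies)
  draws <- .draw_rpm(rpm, length(per_copy))
  pairs$n_reads <- as.integer(tapply(draws, factor(per_copy, levels = seq_len(nrow(pairs))), sum))

  keep <- pairs$n_reads > 0L
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) {
    attr(empty, "origin") <- data.frame(droplet = integer(0),
                                        barcode_id = integer(0),
                                        template_id = character(0))
    return(empty)
  }

  ridx <- rep.int(seq_len(nrow(pairs)), pairs$n_reads)
  templates <- pairs$sequence.x[ridx]

  # Within-droplet chimeras: recombine with another template of the same
  # droplet at a uniform breakpoint.
  if (error$chimera_rate > 0) {
    chim <- which(stats::runif(length(ridx)) < error$chimera_rate)
    for (i in chim) {
      d <- pairs$droplet[ridx[i]]
      others <- unique(mols$sequence[mols$droplet == d &
                                     mols$sequence != templates[i]])
      if (!length(others)) next
      partner <- others[sample.int(length(others), 1L)]
      L <- min(nchar(templates[i]), nchar(partner))
      bp <- sample.int(L - 1L, 1L)
      templates[i] <- paste0(substr(templates[i], 1L, bp),
                             substr(partner, bp + 1L, nchar(partner)))
    }
  }

  i1_t <- substr(templates, 1L, read_len)
  r2_t <- .revcomp(substr(templates, nchar(templates) - read_len + 1L,
                          nchar(templates)))
  r1_t <- pairs$sequence.y[ridx] # barcode sequence (30 nt)

  r1 <- .apply_substitutions(r1_t, 30L, error)
  i1 <- .apply_substitutions(i1_t, read_len, error)
  r2 <- .apply_substitutions(r2_t, read_len, error)

  out <- data.frame(read_id = sprintf("M%08d", seq_along(ridx)),
                    r1 = r1$seq, q1 = r1$qual,
                    i1 = i1$seq, qi1 = i1$qual,
                    r2 = r2$seq, q2 = r2$qual,
                    stringsAsFactors = FALSE)
  attr(out, "origin") <- data.frame(droplet = pairs$droplet[ridx],
                                    barcode_id = pairs$barcode_id[ridx],
                                    template_id = pairs$template_id[ridx],
                                    stringsAsFactors = FALSE)
  out
}

#' Write a simulated run as three synchronized FASTQ files
#'
#' Records are order-synchronized across R1 (barcode), I1 (16S forward) and
#' R2 (16S reverse) with matching read ids, Phred+33. Ground-truth tables
#' are written alongside when supplied.
#'
#' @param triplets Read triplets from [simulate_reads()].
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @param truth Optional [simulate_droplets()] truth to serialize as TSV.
#' @return Named list of written paths.
#' @export
write_run <- function(triplets, dir, prefix = "sim", truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- triplets$read_id
    ok <- tryCatch({
      Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                  qualities = Biostrings::BStringSet(quals))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("failed writing FASTQ '", path, "': ",
                          conditionMessage(ok))
    path
  }
  paths <- list(
    r1 = write_one(triplets$r1, triplets$q1, file.path(dir, paste0(prefix, "_R1.fastq"))),
    i1 = write_one(triplets$i1, triplets$qi1, file.path(dir, paste0(prefix, "_I1.fastq"))),
    r2 = write_one(triplets$r2, triplets$q2, file.path(dir, paste0(prefix, "_R2.fastq")))
  )
  if (!is.null(truth)) {
    tw <- function(df, name) {
      p <- file.path(dir, paste0(prefix, "_", name, ".tsv"))
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    paths$truth_barcodes <- tw(truth$barcodes, "truth_barcodes")
    paths$truth_cells <- tw(truth$cells, "truth_cells")
    counts <- data.frame(strain_id = names(truth$strain_counts),
                         cells = as.numeric(truth$strain_counts))
    paths$truth_strain_counts <- tw(counts, "truth_strain_counts")
  }
  paths
}
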