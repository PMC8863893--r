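# Packaged synthetic mock community: 10 strains carrying 16 distinct
# V3-V4 variants, including two within-strain pairs that differ by a
# single base — the structure that stresses both single-base resolution
# and co-occurrence linkage of multi-copy genomes.

.substitute_base <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  # deterministic single-base neighbour: next base in A<C<G<T order
  new <- .BASES[(match(old, .BASES) %% 4L) + 1L]
  substr(seq, pos, pos) <- new
  seq
}

#' The packaged 10-strain mock community
#'
#' A deterministic synthetic community of 10 strains carrying 16 distinct
#' ~450 nt 16S V3-V4 variants: six single-variant strains, two two-variant
#' strains whose variants differ by exactly one base, and two three-variant
#' strains; copy numbers range from 1 to 3. Concentrations are set so the
#' default encapsulation ([mock_encapsulation()]) loads cells at
#' lambda ~ 0.21.
#'
#' @param total_cells Total cells the concentrations are scaled to within
#'   the default emulsion volume. Default 4200.
#' @return A [community_spec()].
#' @export
mock_community <- function(total_cells = 4200) {
  set.seed(104729L) # fixture definition is deterministic
  base <- .random_dna(14L, 450L)
  weights <- c(1.2, 0.6, 0.9, 1.5, 0.8, 1.0, 1.5, 1.5, 1.2, 0.8)
  encaps <- mock_encapsulation(n_cells = total_cells)
  conc <- weights / sum(weights) * total_cells / encaps$emulsion_volume
  strains <- list(
    strain_spec("S01", base[1L], 1L, conc[1L]),
    strain_spec("S02", base[2L], 2L, conc[2L]),
    strain_spec("S03", base[3L], 1L, conc[3L]),
    strain_spec("S04", base[4L], 3L, conc[4L]),
    strain_spec("S05", base[5L], 1L, conc[5L]),
    strain_spec("S06", base[6L], 2L, conc[6L]),
    # two-variant strains: one-base-apart pairs
    strain_spec("S07", c(base[7L], .substitute_base(base[7L], 101L)),
                c(2L, 1L), conc[7L]),
    strain_spec("S08", c(base[8L], .substitute_base(base[8L], 333L)),
                c(1L, 1L), conc[8L]),
    # three-variant strains
    strain_spec("S09", base[9:11], c(2L, 1L, 1L), conc[9L]),
    strain_spec("S10", base[12:14], c(1L, 1L, 1L), conc[10L])
  )
  community_spec(strains)
}

#' Default encapsulation for the packaged mock run
#'
#' 20,000 droplets of 120 um (0.905 nl; ~18.1 ul of emulsion) loaded with
#' 2,800 barcodes (lambda ~ 0.14, ~93% singleton) and ~4,200 cells
#' (lambda ~ 0.21, ~90% singleton) — the same occupancy regime as a real
#' run, scaled down ~56-fold in droplet count.
#'
#' @param n_droplets Droplet count. Default 20000.
#' @param n_barcodes Barcode molecules. Default 2800.
#' @param n_cells Nominal cell load. Default 4200.
#' @return An [encapsulation_spec()].
#' @export
mock_encapsulation <- function(n_droplets = 20000, n_barcodes = 2800,
                               n_cells = 4200) {
  encapsulation_spec(droplet_diameter = 120,
                     emulsion_volume = n_droplets * droplet_volume(120) / 1e3,
                     n_barcodes = n_barcodes,
                     n_cells = n_cells)
}

#' Simulate a run and write it to disk
#'
#' Convenience driver: Poisson encapsulation, read emission and FASTQ +
#' ground-truth output in one call.
#'
#' @param community A [community_spec()]. Default [mock_community()].
#' @param encaps An [encapsulation_spec()]. Default [mock_encapsulation()].
#' @param error An [error_model()].
#' @param rpm A [reads_per_molecule()] distribution.
#' @param seed Integer seed driving both encapsulation and read emission.
#' @param dir Output directory.
#' @param prefix File prefix. Default `"sim"`.
#' @return List with `paths` (FASTQ/truth files), `truth` and `n_reads`.
#' @export
simulate_run <- function(community = mock_community(),
                         encaps = mock_encapsulation(),
                         error = error_model(),
                         rpm = reads_per_molecule(),
                         seed = 1L, dir, prefix = "sim") {
  truth <- simulate_droplets(community, encaps, seed = seed)
  triplets <- simulate_reads(truth, community, error = error, rpm = rpm,
                             seed = seed + 1L)
  paths <- write_run(triplets, dir, prefix = prefix, truth = truth)
  list(paths = paths, truth = truth, n_reads = nrow(triplets))
}
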