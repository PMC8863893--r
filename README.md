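# barbiq

Cell-based identification and absolute quantification of bacteria from
cellularly barcoded droplet 16S rRNA sequencing.

## The problem

16S amplicon sequencing counts amplified gene molecules, not cells. That
breaks down twice: 16S copy number varies between taxa (1–15 per genome,
often unknown), and one genome can carry several distinct 16S variants
that a gene-based analysis (OTU/ASV) reports as several taxa. The
droplet-barcoding strategy implemented here fixes both by construction:
single cells are co-encapsulated with barcode molecules in ~120 µm
droplets, each cell's 16S genes are amplified and linked to its droplet's
barcode in a single in-droplet step, and sequencing reads are then grouped
per barcode. Counting barcode clusters counts cells; 16S variants that
consistently share barcodes are reunited into one **cell-based OTU
(cOTU)**. Anchoring the counts to an external (ddPCR-style) total yields
absolute cells per mg or µl.

`barbiq` is for people building or validating such pipelines: it contains
the full computational chain plus a droplet-sequencing simulator with
ground truth, so every stage is testable without instrument data.

## The core models

* **Poisson occupancy.** With `n` items in `N_d` droplets, per-droplet
  occupancy is `K ~ Pois(λ)`, `λ = n/N_d`. The singleton fraction
  `P(K=1 | K≥1) = λe^{-λ}/(1-e^{-λ})` and the count-inflation factor
  `p1 + 2(1-p1)` (or exactly `λ/(1-e^{-λ})`) quantify how close the run is
  to one-item-per-droplet.
* **Co-occurrence linkage.** Two Bar sequences seen in `n_i` and `n_j` of
  `N` barcodes co-occur `n_i·n_j/N` times under independence. Pairs are
  tested with an upper-tail exact binomial p-value
  (`X ~ Binom(n_max, n_min/N)`), BH-corrected, and linked when FDR < 0.05
  and the co-detection fraction `n_co/min(n_i,n_j) ≥ 0.5`; connected
  components are the cOTUs.
* **Noise and differences.** Technical noise is judged by
  `R_mc = log10(CV²) − log10(CV²_Poisson)`; a pair of counts is
  differential when it falls outside the two-sided 99.9% Poisson envelope
  *and* changes ≥2-fold. Median-of-ratios size factors, Bray–Curtis
  dissimilarity and analytic rarefaction round out the statistics.

## Worked example

Occupancy arithmetic at a real run's loads (160,000 barcodes, 240,000
cells, 960 µl at 0.85 nl per droplet):

```r
library(barbiq)
spec <- encapsulation_spec(emulsion_volume = 960, n_barcodes = 160000,
                           n_cells = 240000, droplet_volume_override = 0.85)
singleton_fraction(lambda_from_spec(spec, "barcode"))  # 0.931
singleton_fraction(lambda_from_spec(spec, "cell"))     # 0.898
multiplicity_factor(0.93)                              # 1.07
```

So ~93% of barcode-occupied droplets hold a single barcode and ~90% of
cell-occupied droplets a single cell; multi-barcode droplets inflate all
counts uniformly by ×1.07, which cancels from relative abundances.

Simulate a run of the packaged 10-strain mock community (16 variants, two
one-base-apart pairs) and process it end to end:

```r
sim <- simulate_run(community = mock_community(),
                    encaps = mock_encapsulation(n_droplets = 5000,
                                                n_barcodes = 700,
                                                n_cells = 1050),
                    error = error_model(substitution_rate = 0.001),
                    rpm = reads_per_molecule("constant", mean = 8),
                    seed = 1, dir = "readme_run")
res <- run_pipeline(sim$paths$r1, sim$paths$i1, sim$paths$r2,
                    total = total_abundance("mock", 2.3e8, "cells/mg"))
nrow(res$bar_sequences)   # 16  -- every simulated variant, exactly
res$qc$n_cotus            # 10  -- one per strain
res$qc$n_linked_pairs     # 8   -- intra-strain variant links
head(res$counts, 4)
#>    cotu_id cell_count
#> 1 cOTU0001         20
#> 2 cOTU0002         27
#> 3 cOTU0003         27
#> 4 cOTU0004         17
head(round(res$abundance / 1e6, 1), 4)
#> cOTU0001 cOTU0002 cOTU0003 cOTU0004
#>     27.5     37.2     37.2     23.4
```

From 3,216 simulated read triplets the pipeline reconstructs 146 droplets
(barcode clusters), recovers all 16 variant sequences byte-identically —
including both single-base pairs, kept apart during clustering and then
linked into their strains' cOTUs by co-occurrence — and counts cells per
cOTU matching the simulator's ground truth
(`expected_detected_counts(sim$truth)`). The `abundance` entries are cells
per mg after anchoring the counts to the supplied total of 2.3×10⁸.

A thin CLI with the same operations ships in `inst/exec/barbiq`
(`poisson`, `simulate`, `run`, `stats` subcommands).

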