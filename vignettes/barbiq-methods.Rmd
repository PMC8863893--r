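---
title: "Models and design choices behind barbiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind barbiq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barbiq)
```

## The measurement problem

Conventional 16S rRNA amplicon sequencing counts amplified gene molecules,
not organisms. Two things break the molecule-to-cell correspondence: 16S
copy numbers differ between taxa (1 to ~15 per genome, often unknown), and
a single genome can carry several distinct 16S sequence variants, which a
gene-based analysis reports as several taxa. Cellular barcoding in droplets
addresses both: individual cells are co-encapsulated with barcode molecules
in ~120 µm droplets, each cell's 16S genes are amplified and physically
linked to the droplet's barcode, and sequencing then reveals, per barcode,
the set of 16S sequences of one cell. Counting barcodes counts cells;
grouping 16S sequences that share barcodes reunites the variants of one
genome into a cell-based OTU (cOTU).

`barbiq` implements the computational side of this design: the Poisson
occupancy models of droplet loading, a simulator producing synthetic runs
with full ground truth, the read-processing pipeline (barcode clustering,
pair merging, consensus calling, error filtering), the co-occurrence model
that builds cOTUs, absolute-abundance anchoring, and the downstream
statistics used to interpret the counts.

## Droplet occupancy

Loading is Poisson: with $N_d$ droplets and $n$ items, the per-droplet
occupancy is $K \sim \mathrm{Pois}(\lambda)$, $\lambda = n/N_d$. The
quantities the package exposes:

* singleton fraction $P(K{=}1 \mid K{\ge}1) = \lambda e^{-\lambda}/(1-e^{-\lambda})$
  (`singleton_fraction()`),
* the count-inflation factor from multi-barcode droplets,
  $p_1 + 2(1-p_1)$ in the truncated-at-two form, or the exact
  $E(K \mid K \ge 1) = \lambda/(1-e^{-\lambda})$ (`multiplicity_factor()`),
* the independence expectation $n_i n_j / N$ of two sequences sharing a
  droplet (`coencapsulation_expectation()`), the null of the cOTU test.

At a typical run's loads — 160,000 barcodes and 240,000 cells in 960 µl —
the barcode singleton fraction is ~93% and the cell singleton fraction
~90%, so multi-occupancy is a small, uniform correction (×1.07 for
barcodes) that cancels from relative abundances. The droplet volume
defaults to the 120 µm sphere (0.905 nl, `droplet_volume()`); because
instruments report a nominal per-droplet volume rather than a droplet
count, `encapsulation_spec()` accepts an override (0.85 nl is the nominal
value for this emulsion chemistry), and the occupancy figures above use
that override.

```{r occupancy}
spec <- encapsulation_spec(emulsion_volume = 960, n_barcodes = 160000,
                           n_cells = 240000, droplet_volume_override = 0.85)
c(barcode = singleton_fraction(lambda_from_spec(spec, "barcode")),
  cell = singleton_fraction(lambda_from_spec(spec, "cell")))
```

## What the simulator emulates — and what it does not

`simulate_droplets()` assigns barcodes, cells of each strain, and ecDNA
fragments to droplets by independent Poisson draws; `simulate_reads()`
emits read triplets (30 nt barcode read; 295 nt forward and reverse 16S
reads) for every (barcode, template) pair sharing a droplet, with:

* a configurable reads-per-molecule distribution (negative binomial by
  default, mean 12, dispersion 10). Amplification is deliberately not
  simulated cycle-by-cycle here: the pipeline consumes only read
  multiplicities and qualities. The sequencing depth per molecule of the
  original instrument runs is not published, so this default is a stated
  assumption of the simulator, not a reproduction.
* substitution-only sequencing errors, i.i.d. per base (default
  $10^{-3}$), with erroneous bases assigned a low Phred score; no indels,
  no quality-by-cycle decay, no index hopping.
* optional chimeras confined to templates of the same droplet (in-droplet
  amplification largely prevents cross-cell chimerism; the default rate is
  0).
* multi-barcode droplets in which every template emits under every
  barcode — the physical mixing behind the uniform ×1.07 inflation. The
  countable ground truth (`expected_detected_counts()`) accounts for it:
  a strain's countable cells are $\sum_d (\text{barcodes in } d) \cdot
  \mathbf{1}\{\text{strain present in } d\}$.

Passing tests on these simulations therefore demonstrate correctness of
the *computational* pipeline under the model's assumptions; they do not
probe indel errors, polymerase bias, droplet-size dispersion, or chimera
rates of real chemistry.

The packaged fixture (`mock_community()`) is a 10-strain community with 16
V3–V4 variants: six single-variant strains, two strains whose two variants
differ by exactly one base, and two three-variant strains, with copy
numbers 1–3. This is the structure that simultaneously stresses
single-base resolution (the one-base pairs must not be merged) and
co-occurrence linkage (they must end up in one cOTU). The default run
(`mock_encapsulation()`) uses 20,000 droplets at the same occupancy regime
as a real run (λ ≈ 0.14 barcodes, λ ≈ 0.21 cells); test problem sizes
elsewhere (400–8,000 droplets, 500–1,000 features, 10⁴–10⁶ Monte-Carlo
draws) were chosen as the smallest that leave the assertions statistically
sharp.

## Pipeline design choices

**Barcode clustering.** Greedy abundance-ordered clustering: unique
sequences sorted by count (descending, lexicographic ties), each joining
the first cluster whose representative is within Levenshtein distance 2,
else founding one. For random 24-mers, distance-2 collisions are
negligible (the expected number of colliding pairs is reported as a
diagnostic, not enforced as a gate), while substitution errors at
realistic rates rarely exceed 2 in 24 bases. Ordering rules make every
clustering step deterministic and reruns byte-identical.

**Pair merging.** Best ungapped overlap (≥ 30 bases, ≤ 10% mismatches)
chosen by maximal matching bases; disagreements resolved toward the
higher-quality base, agreements keep the maximum quality. Ungapped is
sufficient because the error model is substitution-only and length
variation between taxa is handled per droplet, not inside a merge; under
an indel-prone chemistry this module would need an aligner.

**Within-barcode clustering at distance 0.** 16S sequences under one
barcode are grouped as exact sequence types. A nonzero radius would merge
the two one-base variants of a two-variant genome inside *every* droplet,
so only one of the pair could ever be called per barcode and the pair
could never co-occur — single-base resolution and variant linkage would
both be lost. Exact-type grouping keeps them separate; sequencing-error
reads form low-support types that the error filter removes instead of
being absorbed into a consensus. The clustering operation itself accepts
any radius for other chemistries.

**Error filtering.** A RepSeq is discarded when supported by fewer than 3
reads or by less than 10% of the dominant RepSeq's reads in its barcode; a
surviving sequence must appear in ≥ 2 barcode clusters to become a Bar
sequence. These thresholds (exposed in `pipeline_config()`) are the
package's declared defaults: at ~12 reads per molecule they make both
false positives (a recurring identical error sequence reaching 3 reads in
2 barcodes) and false negatives (a true variant missing them) rare.

**cOTU linkage.** For each pair of Bar sequences sharing at least one
barcode, the upper-tail exact binomial p-value of the observed co-detection
count against the independence null ($X \sim \mathrm{Binom}(n_{\max},
n_{\min}/N)$), Benjamini–Hochberg across all tested pairs; a pair links
when the adjusted p-value is below 0.05 *and* the co-detection fraction
$n_{co}/\min(n_i, n_j)$ is at least 0.5. The fraction gate encodes the
biology — variants of one genome co-occur in essentially every droplet
holding the cell — and protects against spurious significance at large
margins. cOTUs are connected components of the linkage graph; bridging
sequences chaining two components are merged, not resolved (reported in
the pair audit). The false-linkage rate under a true independence null is
verified to respect the FDR level in the test suite.

**Counting and anchoring.** A cOTU's cell count is its number of linked
barcode clusters; a barcode holding k distinct cOTUs contributes one cell
to each (co-encapsulated cells are distinguishable by sequence).
Absolute abundance is count/total × externally measured total (ddPCR-style
anchor); totals are always inputs. The contamination rule removes a cOTU
whose control abundance reaches 10% of its sample abundance — the control
comparison is part of the method, the 10% threshold is this package's
configurable default. In ecDNA (fragment) mode each barcode–sequence link
is one fragment; fragment-only sequences are reported as unassigned Bar
sequences, never as new cOTUs, and the per-cOTU ecDNA/cell ratio is
emitted when both tables exist.

## Downstream statistics

* `size_factors()`: median-of-ratios normalization over features positive
  in all samples.
* `bray_curtis()`, `rarefied_richness()`: the standard dissimilarity and
  the analytic hypergeometric rarefaction expectation
  $E(S) = \sum_i (1 - \binom{N-N_i}{n}/\binom{N}{n})$, both cross-checked
  in the tests against vegan as an independent oracle.
* `technical_noise()`: replicates are depth-equalized by subsampling to
  the smallest total, then each feature's $CV^2$ is compared with the
  Poisson expectation through
  $R_{mc} = \log_{10}(CV^2) - \log_{10}(CV^2_{Poisson})$,
  $CV^2_{Poisson} = 1/\text{mean}$; a per-feature Poisson-simulated
  reference distribution is returned for comparison. Pure counting noise
  gives $R_{mc}$ centred at 0.
* `sampling_envelope()` / `classify_differential()`: a pair of counts is
  *differential* when it falls outside the two-sided Poisson quantile
  envelope (99.9% by default) *and* changes at least 2-fold, sub-classed
  at 10-fold. How exactly the envelope is drawn around the diagonal is
  under-specified in the source material; the declared construction here
  is symmetric — b must lie inside the quantile band implied by a, and a
  inside the band implied by b. Formal differential testing with shrinkage
  (DESeq2-style) is intentionally not re-implemented; only the ≥5-counts-
  in-≥3-samples prefilter (`prefilter_counts()`), the size factors, and
  the envelope rule are part of this package.
* `pcr_error_sim()`: branching-process accumulation of polymerase errors
  over PCR cycles. Each duplication is semiconservative: both daughter
  duplexes contain one newly synthesized strand, so both draw
  $\mathrm{Binom}(L, r)$ fresh substitutions, giving an expected
  $L \cdot r \cdot n_{cycles}$ substitutions per sampled clone (≈1.35 for
  a 450 nt template, $r = 10^{-4}$, 30 cycles). The pool is capped at
  $10^5$ molecules with uniform lineage subsampling, which leaves the
  per-lineage distribution unchanged in expectation. This is the model
  that rationalizes why cloned-and-Sanger-sequenced amplicons sit one or
  two substitutions away from the true template.

## Numerical and degeneracy conventions

Rarefaction uses `lchoose()` differences; features that cannot be absent
from a subsample contribute exactly 1. `singleton_fraction(0)` returns the
limit 1 with a warning. Identical replicates give $CV^2 = 0$ and an
undefined $R_{mc}$ (returned as `NA`, skipped with a note). Zero-count
pairs have no defined fold change and are never differential. Every greedy
tie anywhere in the pipeline is broken (count descending, lexicographic
ascending), so identical inputs and configuration produce byte-identical
outputs, serialized with the run manifest.

## Known limitations

* Substitution-only error handling end to end; indel-prone platforms
  would defeat both the merger and exact-type grouping.
* The error-filter and linkage thresholds are declared defaults tuned for
  the simulator's depth regime, not recovered instrument settings.
* Three-way co-occurrence is handled only through pairwise links and
  transitive components; a sequence bridging two genomes' variant sets
  would merge their cOTUs.
* Droplet volume polydispersity and dead volume are not modeled; the
  occupancy model treats all droplets as equal-volume.
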