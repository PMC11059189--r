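---
title: "Models and methods behind scContacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scContacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scContacts analyzes per-cell chromatin contact lists — the output of
single-cell whole-genome chromosome-conformation assays — to describe
how a cell population's 3D genome is organized and how that
organization changes across donor age. This vignette explains the
statistical models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable option existed.

## Data model and coordinates

A cell is a `ContactSet`: a list of contacts (chromA, posA, chromB,
posB) plus donor, age, sex and species. Input pairs files use 1-based
positions, following the dominant contact-file convention; bins are
0-based half-open internally, and `assignBin()` defines the bridge
(`ordinal = floor((pos - 1)/binSize)`). Contacts are canonicalized on
read (chromA ≤ chromB in genome order, posA ≤ posB within a
chromosome); canonicalization is idempotent, and a write/read round
trip is exact. Contacts on chromosomes absent from the genome are
skipped with a warning rather than aborting the run, so real-world
scaffolds and patch contigs do not kill a batch. Contacts with both
endpoints at the same position are kept: they carry no distance signal
and fall out of the statistics naturally.

Ages are stored with an explicit unit flag (years or postnatal days)
and converted as 1 day = 1/365 year wherever species are compared,
because human cohorts are described in years and mouse cohorts in
postnatal days.

## scA/B: single-cell compartment scores

For bin *b* of cell *c*, `computeScAB()` averages the reference
compartment track value of the partner bins over all contacts with one
endpoint in *b*. Three choices matter:

* **Within-region exclusion.** Contacts whose two endpoints lie in the
  same region (same bin; optionally ± `exclusionRadius` bins, default
  0) are excluded, so the score reports long-range structure rather
  than local density.
* **Symmetric attribution.** Each contact contributes to both endpoint
  bins. The score is a mean, so duplicating a cell's contact list
  leaves it unchanged.
* **Support masking.** Bins with fewer than `minContacts` (default 5)
  contributing partners are masked rather than reported noisily.

The reference track is any per-bin value in [0, 1] with A-like bins
high — a CpG-density rank is the usual choice for real data, and the
generator's own track serves for synthetic data. The score is the raw
track mean by default; no per-cell z-scoring is applied, because the
score is already on the track's scale and cross-cell standardization
would erase genuine global shifts. A per-cell rank-normalization flag
(`rankNormalize`) is available for data with strong coverage artifacts.

Values are stored in an `ScABMatrix`, a `SummarizedExperiment` with
bins as rows, cells as columns, and assays `scab` and `support`.
PCA requires a complete matrix: `imputeMissing()` fills masked entries
with bin means (default; cell means optional) and drops bins never
observed in any cell. Stage means, by contrast, simply omit masked
entries — imputation is confined to the embedding step where it is
unavoidable.

## Stage typing

`embedScAB()` runs centered (unscaled) PCA on cells × bins. Cells
scoring fewer than 200 bins are excluded first (configurable QC gate);
components are sign-fixed deterministically, and PC1 is oriented to
correlate positively with log age when ages are known, so "later in
life" is consistently positive. `clusterStages()` applies Ward
(`ward.D2`) hierarchical clustering to the top 10 PCs — deterministic,
no random initialization — with *k* supplied by the user: the number of
stages in a population is a finding, not an algorithmic constant.
`orderStagesByAge()` relabels clusters S1…Sk by ascending median donor
age (ties broken by cluster id; ageless clusters ordered last and
flagged). Age associations use Pearson's r against log10(age in years),
because lifespans are naturally log-spaced: the same fold-change in age
separates infancy from childhood as separates middle from old age.
A 2-D view for plotting is taken from the first two PCs; it is never
used for assignment.

## Contact-distance and inter-chromosomal statistics

`distanceProfile()` reports the fraction of intra-chromosomal contacts
spanning at least 10 Mb (inclusive threshold). Inter-chromosomal
contacts have no genomic distance, so the denominator is
intra-chromosomal contacts only — a deliberate interpretation the
generator shares, so calibration round-trips are well-defined.

Group contrasts use the two-sided Mann–Whitney U test: exact for small
untied samples (both n ≤ 20), otherwise the normal approximation with
continuity and tie correction. The test suite cross-checks the exact
branch against an explicit enumeration over all label splits.

`interchromEnrichment()` compares observed chromosome-pair contact
counts with a marginal-product null: m_i is chromosome i's
inter-contact endpoint count divided by 2, and expected(i, j) =
T·m_i·m_j / Σ_{k<l} m_k·m_l, which by construction sums to the observed
total T. Contact marginals are used instead of chromosome lengths so
coverage differences between chromosomes do not masquerade as
enrichment. This choice has a quantitative consequence worth knowing:
when a hub spans a large fraction *h* of the genome, part of its weight
is absorbed into the marginals, and the observed/expected ratio of hub
pairs approaches w/(1+h)² rather than the raw pair weight w. The hub
score (mean pairwise enrichment per chromosome) is therefore reported
as a continuous quantity and never thresholded into a "hub set".

Aggregated maps (`aggregateMap()`) sum binned contacts over a cell
group for one chromosome, a chromosome pair, or genome-wide
inter-chromosomal scope; symmetric scopes mirror off-diagonal entries
(each off-diagonal contact counted twice, stated in the file header).

## Dynamic regions and trajectories

`stageMeanScAB()` averages unmasked scA/B per bin per stage; a bin is
eligible only when supported by ≥ 10 cells in every stage, because
stage means from sparse support are unstable. `dynamicRegions()` scores
eligible bins by the range (max − min) of their stage means — chosen
over variance for interpretability; variance is available as an option
— and selects the top `round(topFrac × eligible)` bins (default 20%),
with ties broken by bin id so selection is deterministic even on
degenerate constant input. `clusterTrajectories()` Ward-clusters the
row-centered profiles of the selected bins and names clusters
"increasing"/"decreasing" by the sign of their mean last-minus-first
change. Gene sets are mapped to bins by interval overlap
(`mapGenesToBins()`, BED-like 0-based half-open input, via
GenomicRanges); a gene spanning a bin boundary contributes both bins.

## Pooled-sample demultiplexing

Donor assignment uses a read-level binomial error model: a read at a
SNP is the alt allele with probability ε for dosage 0, 0.5 for dosage
1, and 1 − ε for dosage 2; missing genotypes contribute probability
0.5; counts multiply the per-read log term. Defaults: ε = 0.01 and an
ambiguity flag when the top softmax posterior (uniform prior) falls
below 0.95 — both normative choices of this package, since no published
values exist for them. The heterozygous-site probability of 0.5
ignores allelic imbalance, adequate at the panel scales used here.
There is no doublet model: genotype-free, doublet-aware demultiplexing
is an existing external tool and out of scope.

Sex calls use the X/autosome endpoint-density ratio (each contact
contributes two endpoints — endpoints approximate reads, since the
package ingests contacts, not alignments). The expectations are
analytic — 1.0 for XX, 0.5 for XY — so a fixed cut at their midpoint
(0.75, configurable) is used rather than mixture fitting.

## The synthetic-data generator

The generator exists so that every analysis stage has ground truth. Its
defaults encode the study conditions the statistics are calibrated to:

* **Distance mixture.** Intra-chromosomal distances are a two-component
  mixture: a truncated power law p(s) ∝ s^(−α) on [10 kb, 10 Mb) (α
  default 1.0 — the published quantity is only the ≥ 10 Mb fraction, so
  the short-range shape is this package's configurable choice) and a
  log-uniform "ultra" tail on [10 Mb, chromosome length] with mixture
  weight fUltra. Chromosomes shorter than 10 Mb draw only the short
  component, and fUltra is rescaled on the remaining chromosomes so the
  genome-wide intra fraction ≥ 10 Mb equals the preset's target.
* **Preset calibration.** fUltra defaults per preset follow the
  published per-cell-type values: human granule S1 0.19 → S5 0.33,
  mouse S1 0.19 → S5 0.34 (intermediate stages interpolated linearly),
  human forebrain neurons 0.15 → 0.16, mouse 0.11 → 0.13, Purkinje 0.09
  → 0.10, microglia 0.34, oligodendrocytes 0.29 (human) / 0.27 (mouse).
* **Placement.** The distance is drawn first and the anchor placed
  uniformly on the admissible interval [1, L − d]. (Reflecting
  out-of-range partners at chromosome ends was considered and rejected:
  reflection changes the realized distance and would bias the ≥ 10 Mb
  fraction the presets are calibrated to.) Anchor and partner positions
  are then placed uniformly within their bins, so realized distances
  differ from the drawn distance by less than one bin — negligible for
  10-Mb-scale statistics and what guarantees exact bin-level
  compartment matching.
* **Compartment preference.** With probability ρ (default 0.7) a
  contact must join two bins of the same effective A/B class
  (effective value ≥ 0.5); matching uses vectorized rejection with an
  exhaustive fallback, so ρ = 1 gives strictly same-compartment
  contacts. The track is block-structured (alternating A/B blocks,
  Poisson block lengths, A values 0.6–1.0, B values 0.0–0.4), and
  designated dynamic bins are re-based into 0.36–0.64 so the stage
  presets' drift sequence (−0.15 … +0.15 for up-bins) flips their class
  at transitions spread across all five stages — which is what makes
  set-mean scA/B trajectories graded and monotone rather than a single
  step.
* **Inter-chromosomal contacts.** A fraction fInter (default 0.10 — not
  a published number; chosen as a realistic inter fraction for
  single-cell Hi-C) of contacts is inter-chromosomal, with pairs drawn
  ∝ length_i · length_j · hubWeight_ij. Granule presets carry the
  9-chromosome human hub (weight rising 1 → 2 across S1 → S5) and a
  6-chromosome mouse hub.
* **Sex dosage.** Male cells halve the X-chromosome weight (single X),
  giving the 0.5 vs 1.0 X/autosome ratio the sex demultiplexer expects.
* **Pools.** Donor genotypes are binomial(2, allele frequency 0.5)
  per SNP; cells observe each SNP with the coverage probability
  (default 0.15, inside the published 10–20% range) and reads flip with
  probability ε.
* **Reproducibility.** One cohort seed; each cell draws from a
  substream derived by stable hashing of its index, so cohorts are
  reproducible and individual cells can be regenerated independently.

What the generator does **not** emulate: TADs, loops and polymer
physics; haplotype phase; coverage hotspots and mappability artifacts;
doublets; donor relatedness or realistic allele-frequency spectra; and
per-cell contact counts at the depth of real experiments (desk-scale
cells carry 5,000–50,000 contacts, not ~600,000, which is why support
masks and eligibility gates matter more here than on real data).
Passing tests on synthetic cohorts therefore demonstrate that the
statistics recover the structure they are defined on — not that real
tissue will show that structure.

## Problem sizes and numerical choices

Test cohorts use 12–100 cells per stage at 10,000–20,000 contacts per
cell; calibration checks use 100–200 cells per preset; the pooled-demux
validation uses 672 cells × 1,000 SNPs at 15% coverage. At 20,000
contacts per cell most 1-Mb bins clear the 5-contact support mask,
which is the regime the default cohort is defined in. Degenerate inputs
are handled deterministically throughout: ties in donor likelihoods are
broken by donor order and flagged ambiguous, ties in dynamic-region
scores by bin id, ties in stage ages by cluster id; cells without intra
contacts, bins without support and chromosomes without inter contacts
propagate as flagged NA rather than silent zeros.

## Known limitations

* scA/B depends on the reference track's quality; with a poor track the
  scores remain well-defined but lose biological meaning.
* The marginal-product null understates enrichment of large hubs (see
  above); comparisons between groups (`enrichmentDelta()`) are the more
  robust readout.
* The stage model assumes one dominant age-ordered axis of variation;
  populations with several independent axes need *k* and the PC count
  chosen with care.
* Demultiplexing assumes the panel's donors are unrelated and the error
  rate is known; related donors shrink likelihood margins in ways the
  ambiguity flag only partially captures.
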