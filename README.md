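# scContacts

Analysis of per-cell chromatin contact lists from single-cell
whole-genome chromosome-conformation experiments (Dip-C style data), for
studies of how the 3D genome of a cell population reorganizes across the
lifespan — the setting in which cerebellar granule cells were shown to
keep remodeling their compartments from infancy to old age. The package
is aimed at computational biologists who have per-cell contact pairs
(plus a chromosome-sizes table and a reference compartment track) and
want compartment scores, structure-stage typing, long-range contact
statistics and pooled-sample demultiplexing in one tested toolchain.

## What it computes

* **scA/B compartment scores.** For cell *c* and 1-Mb bin *b*, the
  single-cell A/B score is the mean reference compartment value of the
  partner bins over all contacts with one endpoint in *b*,

  scA/B(c, b) = (1/|P_b|) Σ_{p ∈ P_b} track(p),

  excluding contacts whose two endpoints fall within the same region, so
  the score reports long-range structure. Bins with fewer than 5
  supporting contacts are masked.
* **Structure stages.** Cells are embedded by centered PCA of their
  scA/B profiles, clustered (Ward), and clusters are relabeled S1…Sk by
  ascending median donor age; Pearson's r between PC1 and log10(age)
  quantifies the age axis.
* **Ultra-long-range contacts.** Per cell, the fraction of
  intra-chromosomal contacts with |pos_B − pos_A| ≥ 10 Mb, compared
  between groups with the two-sided Mann–Whitney U test.
* **Inter-chromosomal hubs.** Observed chromosome-pair contact counts
  against a marginal-product null, expected(i,j) = T·m_i·m_j / Σ_{k<l}
  m_k·m_l with m_i the endpoint marginal; hub score = mean pairwise
  enrichment.
* **Dynamic regions.** Per-bin stage means; the top 20% of eligible bins
  by range (max − min) across stages, clustered into increasing and
  decreasing trajectories; gene-set trajectories with consecutive-stage
  U tests.
* **Pop-C demultiplexing.** Pooled cells are assigned to donors by SNP
  genotype likelihood (read-level error model: P(alt | dosage 0, 1, 2) =
  ε, 0.5, 1 − ε) and to sex by the X/autosome contact-density ratio
  (expected 1.0 for XX, 0.5 for XY).
* **Synthetic cohorts.** A calibrated generator produces cells with
  stage-dependent distance mixtures, compartment-biased partner choice,
  hub-weighted inter-chromosomal pairs, X dosage by sex and sparse SNP
  observations, with full ground truth — so every stage of the pipeline
  is testable without external data.

## Worked example

```r
library(scContacts)

## a five-stage synthetic cohort on the packaged human-like genome
design <- defaultCohortDesign("human", nCellsPerStage = 25,
                              nContacts = 20000, seed = 19)
cohort <- simulateCohort(design)

## scA/B scores, embedding, stage typing
m   <- scabMatrix(cohort$cells, design$track)
emb <- embedScAB(imputeMissing(m))
cl  <- clusterStages(emb, k = 5)
asg <- orderStagesByAge(cl, emb$ages)

mclust::adjustedRandIndex(asg$assignment$stage, cohort$metadata$stage)
#> [1] 0.9797518
ageCorrelation(emb$scores[, 1], emb$ages)$r
#> [1] 0.9610662

## ultra-long-range fractions per stage
frac <- sapply(cohort$cells, function(x) distanceProfile(x)$fraction)
round(100 * tapply(frac, cohort$metadata$stage, mean), 1)
#> human-S1 human-S2 human-S3 human-S4 human-S5
#>     19.2     22.6     26.1     29.4     33.0
```

The adjusted Rand index of ~0.98 says the scA/B-based clustering
recovers the generator's stage labels almost perfectly; PC1 correlates
with log age at r ≈ 0.96, reproducing the age axis the stages are
defined by; and the per-stage ultra-long-range fractions climb from
~19% (S1) to ~33% (S5), the published granule-cell range the presets are
calibrated to.

An end-to-end run (`runPipeline(list(outDir = "run"))`) writes the
metadata, sex-demux, scA/B, stage, distance-statistic and
dynamic-region tables into one directory, each stamped with the config
hash and seed.

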