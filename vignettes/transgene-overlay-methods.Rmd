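---
title: "Methods: projection identity from viral transgene barcodes"
author: "TransgeneOverlay package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projection identity from viral transgene barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The overlay model

A retrogradely infecting virus injected into brain structure *A*
expresses its transgene in the cell bodies of neurons that project to
*A*. In a droplet RNA-seq experiment on the source structure, the
transgene mRNA is captured like any endogenous transcript, so each
barcode's distribution over cells encodes connectivity. The analysis
rests on three assumptions:

1. **Barcodes are detectable and discriminable.** The transgene must be
   present in the alignment reference (hence reference augmentation)
   and sufficiently different from every other barcode that reads
   cannot align ambiguously (hence the k-mer discriminability check at
   read-length scale, default *k* = 90 nt).
2. **Barcodes do not shape the clustering.** Clusters must reflect the
   endogenous transcriptome, not infection status; transgene features
   are therefore excluded from highly-variable-gene selection, PCA, and
   the neighborhood graph, and this exclusion is asserted at every
   entry point rather than left to convention.
3. **Infection preserves the transcriptional ground state.** If
   infection skewed endogenous expression, transgene⁺ cells would
   segregate from transgene⁻ cells within a cluster. The
   `perturbationCheck()` test makes this falsifiable: a within-cluster
   Mann–Whitney comparison per endogenous gene with
   Benjamini–Hochberg (BH) correction, expecting zero significant
   genes.

## Positivity, assignment, and the ambient diagnostic

A cell is transgene-positive when its raw barcode count is at least
θ reads (default θ = 1, i.e. any aligned read; configurable upward for
noisy data — with the caveat that a barcode detected by a single read
dataset-wide is then formally "positive" in one cell, which the
breadth and enrichment statistics will correctly treat as
uninformative).

Projection assignment uses the upper-tail hypergeometric probability of
observing at least the cluster's number of positives if the dataset's
positives were placed at random, one test per cluster, BH-corrected
across clusters within each transgene (one decision family per
barcode). A cluster is assigned when *q* < α (default 0.05) and its
positive fraction exceeds the global fraction.

Ambient RNA — free transcript released when the injection site is
included in the dissection — contaminates droplets regardless of their
content. Two signatures separate it from genuine retrograde labeling:

* **Breadth.** An ambient barcode appears in virtually every cluster;
  a retrograde one concentrates in its projection population(s). The
  default breadth cutoff is 0.9 (fraction of clusters with ≥ 1
  positive).
* **Compartment neutrality.** Retrograde viruses infect neurons, so
  the transgene⁺ set should be depleted of the non-neuronal
  compartment; ambient contamination is compartment-blind. The test
  is a one-sided two-proportion *z*-test of the non-neuronal share
  among positives versus negatives (its *z*² equals the Pearson
  chi-square of the same 2×2 table).

The verdict is `retrograde_consistent` when depletion holds at level α;
`ambient_suspect` when it does not *and* breadth ≥ 0.9; `undetected`
with zero positives. We added a fourth value, `inconclusive`, for the
remaining corner (no depletion, narrow breadth — e.g. a barcode with a
handful of positives): forcing that case into either substantive
verdict would overstate the evidence.

**Construction of the 2×2 table.** The default is positive vs negative
rows (independent rows, `versus_negative`), with no continuity
correction; positives-versus-total and a Yates correction are options.
Published analyses of this design report percentages of positives
against dataset totals, and their printed contamination p-values are
not jointly recoverable from the printed counts under any single
obvious 2×2 construction; we therefore fixed the statistically
defensible independent-rows form and treat those particular p-values as
descriptive, not as reference values. The *specificity* chi-squares
(marker⁺ shares between two projection populations), by contrast,
reproduce exactly from printed counts under Pearson's statistic without
correction, which is why that is the default for `chisq2x2()`.

## Validation arithmetic

`coexpressionRate()` reports round-half-up integer percentages
(`floor(x + 0.5)`), and compartment percentages are reported at two
decimals with the same rule, matching the conventions of FISH
co-expression reporting. Base R's `round()` rounds half to even and
would disagree on exact halves.

# Preprocessing stack

| stage | default | notes |
|---|---|---|
| QC bounds | presets `v1` (200–6,000 genes, 750–30,000 counts), `sc` (300–9,000, 750–50,000), `vm` (300–5,000, 500–20,000) | all with a 5% mitochondrial cap; genes counted over endogenous + transgene features |
| doublets | flags are inputs | detection itself is out of scope; the simulator provides truth flags |
| normalization | total 10⁴, `ln(1 + x)` | zero-total cells are flagged at metrics and a hard error here — failing loudly between stages beats silent NaN propagation |
| TF-IDF | `TF × ln(N / n_g)` | natural log, no smoothing; a gene present in every cell (or none) gets weight 0. The truncated published formula is consistent with this standard definition given its variable glossary; the log base is not stated anywhere, so we fixed base *e* and keep the stage optional, off the main clustering path |
| HVG | top 2,000 | dispersion (variance/mean of log expression) z-scored within 20 equal-frequency mean bins; ranked descending, ties broken by gene index — no named method exists in the source description, so we chose a deterministic conventional one |
| scaling | zero mean, unit variance | population (1/n) variance, so a {0, 2} half-split gene scales to ±1; zero-variance genes map to zeros |
| PCA | 50 components | component signs fixed by the largest-magnitude loading, making the embedding reproducible across BLAS implementations |
| kNN graph | k = 15, Euclidean in PC space | directed edges symmetrized by union, unweighted — the simplest contract; ties broken by cell index |
| Leiden | resolution 0.6, modularity objective | community detection is delegated to igraph behind a seeded, resolution-parameterized interface; the contract tested is determinism and the modularity guarantee, not a specific refinement schedule |
| dendrogram | complete linkage, `1 − r` | Pearson correlation between cluster-centroid PC vectors over the top 50 components; centroids are the conventional aggregation |

# Marker ranking and merging

The one-vs-rest Mann–Whitney *U* is computed from global per-gene ranks
(the rest group is the complement of each cluster, so one rank pass
serves all clusters). The reported score is the standardized,
tie-corrected *U* (*z*); p-values use the normal approximation with tie
and continuity correction, except that samples of at most 10 per side
without ties use the exact *U* distribution — giving an exactly
testable small-sample path (verified against full permutation
enumeration to 1e-9 in the test suite). BH is applied across genes
within each cluster's comparison.

Cluster merging takes the top-50 marker sets, computes pairwise Jaccard
similarity |A∩B| / |A∪B|, and merges the transitive closure of pairs at
or above 0.8. The published rule ("80% cutoff on mutual presence of the
top 50 unique genes … using the Jaccard similarity score") is ambiguous
between Jaccard ≥ 0.8 and raw overlap |A∩B|/50 ≥ 0.8 (which is Jaccard
2/3); both are implemented (`method = "jaccard"` / `"overlap"`), with
Jaccard the default. The accompanying visual heatmap/dendrogram
inspection of the original workflow is deliberately not modeled — only
the quantitative rule defines behavior here. Merged labels are
renumbered contiguously by smallest member label.

Final markers quantify "unique, highly expressed, expressed in the
majority of the cluster" as: in-cluster expressing fraction ≥ 0.5,
out-of-cluster fraction ≤ 0.2, and appearing in exactly one cluster's
surviving list. The 0.5/0.2 values are our documented, configurable
quantification of those words.

# The droplet simulator

`simulateDroplets()` emulates the statistical structure the overlay
method assumes:

* endogenous counts: negative binomial with mean
  `sizefactor × basemean × fold` and variance `μ + φμ²` (φ = 0.4 by
  default); per-gene base means log-normal (meanlog −0.7, sdlog 1);
  per-cell size factors log-normal (sdlog 0.3);
* marker genes: fold enrichment (default 20× in the bundled fixture)
  over a baseline floored at 0.1 counts — markers are modeled as
  reliably detectable in their population and largely absent
  elsewhere, as real cell-type markers are; without the floor, a
  "marker" drawn at a negligible base mean would be unexpressed even
  where enriched;
* transgenes: a cell labeled with probability *p*(population) receives
  NB(sizefactor × 5, φ) barcode counts; every cell additionally
  receives Poisson(ambient rate × sizefactor) counts — ambient
  contamination is uniform by construction, which is exactly the null
  the compartment diagnostic tests;
* mitochondrial features: Poisson counts targeting a Beta(2, 80)
  per-cell fraction in expectation;
* doublets (5%): the sum of two uniformly drawn singlet profiles,
  inheriting the compartment and primary population of the larger
  parent (ties keep the first); flags are carried as ground truth for
  the QC stage.

The default fixture has five populations (Exc1 500, Exc2 400, Inh1 400
neuronal; Astro 400, Oligo 300 non-neuronal), 1,500 endogenous genes
with 25 markers each, and three transgenes: GFP labels Exc1 at 0.6, Cre
labels Exc2 at 0.5, and tdTomato is ambient-only at rate 0.15 —
mirroring a design with two informative barcodes and one contaminated
one. Where the source experiments report no quantitative value (ambient
rates, labeling probabilities), these defaults are one-time choices of
realistic magnitudes, not fitted quantities.

**What the simulator does not model:** sequencing reads or UMI
collisions, batch effects, compartment-specific ambient composition,
within-population substructure, or empty droplets. Passing tests on
simulated data therefore demonstrate that the pipeline's inferences are
correct *under its own model assumptions* — they do not certify
performance on real tissue, where ambient RNA is gene-dependent and
cluster granularity is contestable.

# Numerical and degenerate-input conventions

* Sequence identity: global alignment, match +1, mismatch −1, linear
  gap −2 per position; identity = matches / alignment length; `N`
  never counts as a match (conservative for ambiguous bases). No
  scoring scheme is published for the reported isoform identity
  percentage, so the scheme is fixed and documented rather than tuned
  to reproduce that number.
* Shared k-mer fraction: Jaccard of the two k-mer sets; a warning flag
  on any nonzero value at read-length *k*.
* Degenerate 2×2 tables (zero margin) carry `NA` statistics and a
  `degenerate` flag rather than a fabricated p-value; `chisq2x2()`
  errors and advises an exact test.
* All-zero cells: flagged at QC metrics (mito fraction defined as 0),
  hard error at normalization.
* Determinism: a single master seed fans out to every stochastic stage;
  TSV outputs format doubles at 6 significant digits so reruns are
  byte-identical.

# Problem sizes used by the test suite

Module tests run on toys (≤ 60 cells) against dense or enumeration
oracles. Pipeline-level properties use the 2,000-cell default fixture:
20 seeded end-to-end runs for projection-assignment recovery and
ambient detection, 20 permutation runs for the perturbation null, and
500 reduced-size replicates (200 cells, 25% non-neuronal, ambient rate
0.12) for the calibration of the one-sided contamination test. These
sizes keep each property estimable with useful Monte-Carlo precision at
desk scale.

# Known limitations

* The contamination diagnostic needs both compartments present and a
  nontrivial number of positives; single-compartment datasets are
  rejected rather than silently passed.
* Hypergeometric enrichment treats cells as exchangeable; strong
  library-size confounding between clusters could bias assignment.
* θ = 1 makes positivity sensitive to index hopping and ambient reads
  by construction — that sensitivity is intentional (the diagnostic,
  not the threshold, is the guard), but users with known hopping
  issues should raise θ.
* Cluster merging considers marker-set overlap only; populations
  differing in a handful of genes can merge at the default cutoff.
* Doublet detection is not implemented; the pipeline consumes flags
  from an external tool or the simulator.
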