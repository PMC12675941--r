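---
title: "Methods: proteome composition, ecological traits, and PGLS over a topology ensemble"
author: "proteoPGLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome composition, ecological traits, and PGLS over a topology ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoPGLS)
```

## What the package estimates

`proteoPGLS` asks whether the amino-acid composition of a clade's
proteomes covaries with two ecological traits: genus-level diet breadth
and the realised thermal maximum (the largest "maximum temperature of the
warmest month" value over a species' occurrence points, in °C). For each
amino acid $a$ and each gene set (whole proteome, orthologous genes,
non-orthologous genes) it fits, per species $s$,

$$z_{s,a} = \beta_0 + \beta_d \ln(\mathrm{diet}_s)
            + \beta_t \ln(\mathrm{temp}_s) + \varepsilon_s,
  \qquad \varepsilon \sim \mathcal{N}(0,\, \sigma^2 \mathbf{C}),$$

where $\mathbf{C}$ is the Brownian-motion covariance implied by the
phylogeny: $C_{ij}$ is the branch-length depth of the most recent common
ancestor of tips $i$ and $j$, and $C_{ii}$ the root-to-tip distance.
Species are not independent observations; the GLS error structure is what
turns a cross-species regression into a defensible comparative test.

## From FASTA to the response

The response is built in three steps, each kept visible in the
`AAProfileSet` container (a `SummarizedExperiment` with assays `rawFreq`,
`standardized`, `zscored`):

1. **Relative frequency.** Residues are pooled over all of a species'
   proteins in the gene set; $f_{s,a}$ is the count divided by the total
   counted residues. Relative (not absolute) frequency is used so species
   with different proteome sizes are comparable — the downstream z-score
   would otherwise absorb genome size. Ambiguity and non-canonical codes
   (`X B Z J U O * -`) are skipped but tallied, so silent data loss stays
   observable; any other character is an error naming the record.
   Every FASTA record is counted; isoforms are not deduplicated, since
   reference proteomes do not always mark them and the effect on pooled
   frequencies is a re-weighting the z-score tolerates.
2. **Codon-redundancy standardization.** Frequencies are divided by the
   number of synonymous sense codons of the amino acid (1 for Met/Trp up
   to 6 for Leu/Ser/Arg; the 20 values sum to 61). Codon multiplicity
   inflates raw frequencies, so this removes a known mutational
   covariate. Because the divisor is constant within an amino acid, the
   subsequent z-score is invariant to it; it matters for the values a
   reader sees, not for inference.
3. **Cross-species z-score.** Each amino acid is centred and scaled
   across species with the sample (n−1) standard deviation — the
   behaviour of base R's `scale()` defaults. A zero-variance amino acid
   cannot be z-scored and is a hard error naming the column; with real
   proteomes (10^5–10^7 residues per species) this only occurs on
   degenerate inputs, and failing loudly beats emitting NaNs.

**Orthology partition.** The orthogroup table (OrthoFinder
`Orthogroups.tsv` dialect) is consumed, never produced. A protein in any
orthogroup counts as orthologous by default — including species-specific
groups, since membership in a group is the only evidence the table
carries; `orthologDef = "multi_species"` restricts orthology to groups
spanning at least two species for users who prefer the stricter reading.
Unassigned proteins form the non-orthologous set. An empty partition for
any species is an error: a species cannot contribute a frequency of
nothing.

## Ecological predictors

**Diet breadth** is the number of distinct host-plant genera, where the
genus is the first whitespace-delimited token of the host name,
case-folded. Hybrid markers and author abbreviations are not parsed;
host databases store binomials, and the first token is the genus in all
ordinary cases. Duplicated records cannot change a distinct count.

**Thermal maximum** is a nearest-cell lookup of a bio5-style grid under
each occurrence point, then the maximum over points. Grid cells are
half-open — closed on their west and north edges — so every point maps to
exactly one cell and points on the east/south outer boundary are
off-grid. Off-grid points and points on missing cells are skipped and
counted in the log, not errors: presence records routinely fall outside a
raster's footprint. No occurrence cleaning (outlier or sea-point
filtering) is applied beyond coordinate-range validation; the maximum is
deliberately taken over all in-range records.

Species lacking either predictor, or a proteome, are excluded with a
logged reason; the analysis set is exactly the coverage intersection.
Fewer than 3 retained species is fatal (no residual degrees of freedom).
Labels are matched after trimming and collapsing spaces/underscores, the
only mismatch Newick convention routinely creates.

## The PGLS fit and its numerical choices

The estimator is the closed form
$\hat\beta = (X^\top C^{-1} X)^{-1} X^\top C^{-1} y$, computed by
whitening with the upper Cholesky factor of $\mathbf{C}$ and never
forming an explicit inverse. Choices worth recording:

* **Log base.** Predictors enter as natural logarithms. Saying a
  predictor is "log-transformed" does not fix a base; a base change
  rescales coefficients but leaves t and p untouched, so inference is
  base-invariant.
* **Branch-length model.** Pure Brownian covariance; no Pagel's λ, OU or
  other signal parameter is estimated. The model is plain PGLS, and the
  generator simulates exactly this structure, keeping the calibration
  experiments interpretable.
* **Near-singular covariance.** If the Cholesky factorization fails, one
  diagonal jitter of at most $10^{-10}\times$ the mean diagonal is
  added; if it still fails the matrix is reported singular. Ensembles of
  calibrated trees occasionally contain zero-length terminal pairs that
  make $\mathbf{C}$ PSD rather than PD; the jitter is far below any
  biological signal.
* **Residual scale.** $\hat\sigma^2$ divides by $n-p$ (not $n$), giving
  the unbiased residual scale that the t-distribution on $n-p$ degrees
  of freedom expects.
* **$R^2$.** One minus the ratio of whitened residual sums of squares
  against the GLS intercept-only fit under the same $\mathbf{C}$ — the
  GLS analogue of the ordinary coefficient of determination, clamped to
  $[0,1]$ against floating-point underflow.
* **Rank checks.** A constant predictor (after log transform) is a rank
  deficiency reported by column name rather than a cryptic solve error.

**Pruning.** Ensemble trees are pruned to the analysis taxa (outgroups
only root the tree and would otherwise distort the covariance scale).
When pruning removes the original root, the excised stem is retained as a
root edge, so root-to-tip distances — and therefore $\mathbf{C}$ — are
exactly the submatrix of the unpruned covariance. Calibrated trees that
are slightly non-ultrametric produce a logged warning and proceed.

## The topology ensemble

The entire 20-regression analysis is repeated for every tree in the
ensemble. Benjamini–Hochberg adjustment is applied within each
(tree, gene set, predictor) family of 20 p-values — each tree yields a
complete analysis, and the reported table presents adjusted p per
predictor column per gene-set block; `bhFamily = "pooled"` widens the
family to everything within a tree and gene set. Adjustment happens per
tree and is then summarized, not the other way round. Each quantity is
aggregated as the **median** across trees (for an even count, the mean of
the two central order statistics) with a **min–max** interval, rendered
`point (low to high)`. The median is robust to the occasional aberrant
topology; the min–max interval makes the ensemble spread legible without
asserting a distributional interpretation. Trees whose fit fails are
dropped with a logged reason; more than 10% failures aborts the run. The
interaction term $\ln(\mathrm{diet})\times\ln(\mathrm{temp})$ is off by
default and available via a flag: the reported model is main-effects.

## What the synthetic generator emulates — and what it does not

`syntheticScenario()` fixes a ground truth: a Yule tree (forward
simulation; the wait before the split from $k$ to $k+1$ lineages is
Exp($k\lambda$), plus one final stretch, so the expected height at rate 1
is $\sum_{k=2}^{n} 1/k$), Brownian log-traits, per-amino-acid regression
coefficients, and Brownian residuals. Defaults are chosen once to mirror
the study design the package targets and are stated here so nobody has to
reverse-engineer them: 35 species; ensemble of 1000 independent Yule
topologies on the same tip set (tree 1 generates the data); birth rate 1;
log diet breadth rooted at $\ln 5$ with rate 0.1 (breadths roughly 1–15
genera); log thermal maximum rooted at $\ln 30$ with rate 0.002
(roughly 25–37 °C); residual rate 0.3 per amino acid; all trait effects
zero (the null regime) unless a `beta` matrix injects them; 300 proteins
per species of mean length 300; ortholog fraction 0.6. Diet breadth is
discretized by `ceiling(exp(·))` (a genus count is an integer ≥ 1) and
temperature rounded to 0.01 °C at generation time, so the round trip
through the emitted CSV/ASCII-grid files is exact by construction — the
ecology round-trip checks test the pipeline, not float formatting.

Trait effects are injected at the level of the z-scored response — the
quantity PGLS consumes — so recovery targets are exact by construction;
`injectInFrequencies = TRUE` additionally tilts the emitted residue
frequencies, exercising the full standardization chain at the cost of
attenuated effects. Random streams are split per component (trees,
traits, residuals, frequencies, proteomes, orthogroups, ecology) from the
master seed, so changing one component's parameters leaves the others'
draws untouched, and identical seeds give byte-identical files.

The generator targets statistical structure, not biological realism: it
does not mimic real codon usage, GC content, gene-length distributions,
isoform structure, spatially autocorrelated occurrence records, or
realistic biogeography. Passing tests therefore demonstrate that the
*method* is implemented correctly and calibrated under its own
assumptions — not that those assumptions hold for any real clade.

## Validation experiments and the sizes they use

The test suite runs, among unit checks: GLS-vs-OLS equivalence on star
phylogenies (100 random instances, 10⁻⁸); brute-force dense-algebra
agreement on 3–6-taxon trees (10⁻¹⁰); covariance-vs-patristic-oracle
agreement and prune/covariance commutation on 50 random trees (10⁻¹²);
BH against its definitional step-up on 1000 random vectors; parameter
recovery on a 128-tip tree (β_diet = −0.3, β_temp = 0.5, 500 replicates,
agreement within 3 Monte-Carlo standard errors); type-I calibration on a
64-tip tree (1000 null replicates; PGLS rejection within [0.03, 0.07] at
α = 0.05 and strictly below the inflated misspecified-OLS rate); and a
full 35-species, 100-tree pipeline run checked for determinism
(byte-identical reruns) and output shape (60 rows, `point (low to high)`
formatting, zero-width intervals for a single-tree ensemble). These sizes
were chosen as the smallest that make the Monte-Carlo bounds sharp enough
to catch sign errors and mis-scaled covariances.

## Known limitations

* Plain Brownian PGLS only: no measurement-error model, no signal
  parameter, no multivariate (all-amino-acids-jointly) regression, no
  model selection. Compositional dependence among the 20 responses is
  acknowledged and ignored, as in the per-amino-acid reporting the
  package reproduces.
* The realised thermal maximum is a proxy: it reflects where a species
  was recorded, not a physiological limit, and inherits every bias of
  occurrence data.
* Orthology is taken at face value from the input table; no inference,
  alignment or tree building is attempted.
* The ensemble treats trees as exchangeable replicates of one topology
  estimate; it propagates, but does not model, phylogenetic uncertainty.
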