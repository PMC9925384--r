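---
title: "Methods: crypt-resolved somatic mutation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crypt-resolved somatic mutation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptomes)
```

This vignette documents the models behind each stage of the pipeline, the
tunable parameters and their defaults, the design choices made where the
procedure was genuinely open, and what the synthetic cohort does and does not
emulate. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The synthetic cohort

Real crypt sequencing data are controlled-access, so the package's input is a
generator whose defaults are the study conditions every downstream check runs
under:

* **Clonality.** A crypt descends from one recent ancestral stem cell, so
  somatic truth VAFs are 0.5 in carrier crypts and 0 elsewhere before read
  sampling. Reads are observed through depth ~ Poisson(`mean_depth`, default
  25) and alt ~ Binomial(depth, VAF).
* **Mutation accrual.** Per-branch counts are Poisson(rate x branch years)
  with per-region rates 51/50/42 SBS per year (duodenum/jejunum/ileum) and
  3.7/2.6/2.3 indels per year. The background signature mixture is
  SBS1/SBS5/SBS18 = 0.30/0.58/0.12: SBS1 and SBS5 as the ubiquitous clock,
  SBS18 at the ~12% share it contributes to small-intestinal burden.
* **Fission trees.** Each patient gets a random binary fission tree with
  fission ages uniform on `fission_age_range`. No generative fission prior is
  established for this tissue; the default `c(1, 10)` years places fission
  predominantly in early life, consistent with colorectal crypt dynamics, and
  keeps branches shared by almost all crypts short. That choice matters: a
  somatic mutation carried by *every* crypt of a patient is statistically
  indistinguishable from a germline heterozygote, so truncal mutations are
  inherently lost to the germline filter (about 0.5–3% of somatic truth under
  the default prior). The fission prior is a free parameter, not an estimate.
* **APOBEC episodes.** With probability 0.163 per branch (the observed
  fraction of signature-positive branches), a burst adds 300 SBS2/SBS13
  mutations, about the 11% share observed in positive adult crypts, including
  one kataegis cluster of 6 mutations within 2 kb placed at TCN-context
  positions.
* **Artifacts.** Systematic artifacts recur in every sample at VAF
  ~Beta(mean 0.03, overdispersion 0.02) — exactly the signal the rho filter
  targets — and a smaller set of mapping artifacts carries failing read
  metrics (alignment score 60–135, clipped fraction 0.5–0.9).
* **Germline.** 1,000 heterozygotes per patient at VAF 0.5 in every crypt; a
  male-X mode (expected VAF 0.95) exercises the sex-chromosome branch of the
  germline test.
* **Context fidelity.** Mutation positions are drawn from the pool of genome
  positions whose pyrimidine-strand trinucleotide matches the drawn channel,
  so spectra remain faithful on short synthetic genomes.

What the generator does **not** emulate: read-level errors and alignment
(reads are summarized as counts), copy-number and structural variation,
non-clonal crypts, chemotherapy signatures, and genome-scale sparsity — the
default 5 Mb genome is ~600x denser per base than a real genome at equal
mutation counts, which is why kataegis simulations use positions drawn at the
2.9 Gb callable-genome scale instead (below). Passing tests demonstrate that
the statistical machinery recovers known structure under the model's
assumptions, not that those assumptions hold in any particular tissue.

## Filter chain

Stages run in order; unevaluable variants (missing metrics, zero aggregate
depth) are conservatively excluded with an audit record.

1. **Read metrics.** Median alignment score >= 140 and < 50% clipped
   supporting reads; indels additionally caller quality >= 300 at positions
   covered by >= 15 reads. Boundaries are inclusive exactly as stated.
2. **Germline.** Alt and depth aggregate across the patient's crypts; a
   one-sided exact binomial test (alternative "less") against p0 = 0.5
   (0.95 on male sex chromosomes) is BH-corrected across all the patient's
   variants, both classes pooled, with somatic classification at q < 1e-5.
   Only aggregates matter, so the test is invariant to sample order and to
   re-splitting counts across samples. The BH family excludes variants
   already failing stage 1.
3. **Overdispersion (rho).** The beta-binomial log-likelihood is maximized
   over rho on a 64-point log-spaced grid on [1e-6, 0.89], with the
   beta-binomial mean fixed at the pooled VAF — the estimator stays
   one-dimensional, mirroring the Shearwater-style filter this stage adapts.
   Variants with rho < 0.1 are artifacts. When the pooled VAF is 0 or 1 the
   likelihood is flat in rho; the lower boundary is returned with a
   degeneracy flag.

## Sensitivity and burden regression

Detection sensitivity is the probability of at least t mutant reads (t = 4
for substitutions, 5 for indels) when depth ~ Poisson(mean coverage) and each
read carries the variant with probability equal to the sample's median VAF.
The Monte-Carlo estimator (100,000 draws) is checked against the closed form
`sum_d Pois(d; lambda) [1 - BinomCDF(t-1; d, v)]` to within 3 Monte-Carlo
standard errors. Burdens divide by sensitivity.

The mixed model regresses adjusted burden on age with region-specific slopes
(`~ 0 + age:region [+ age:celiac]`) and a random age slope per patient. A
random slope rather than a random intercept is the primary structure because
between-patient rate variation is the biological quantity of interest; on
singularity the fit degrades to a random intercept and finally to a
fixed-effects-only `lm`, flagged in the result. Confidence intervals are
normal-approximation Wald; nested comparisons refit by ML and use a
likelihood-ratio test. QC drops crypts under 15x coverage (burden mode) and
additionally celiac patients, children and chemotherapy-exposed donors in
dynamics mode, where constant-rate and fixed-crypt-size assumptions are
doubtful.

## Phylogeny and branch timing

Tree building is a greedy perfect-phylogeny construction: variants are
genotyped per crypt (VAF >= 0.25 with >= 3 alt reads separates clonal ~0.5
from absent at depth 25), grouped by crypt-sharing pattern, and patterns are
accepted in decreasing support order when nested or disjoint with everything
already accepted; the laminar family defines the tree, star-shaped when
nothing is shared. Ties break lexicographically, making the construction
deterministic.

Branch assignment maximizes, per variant, the product over crypts of
Binomial(alt; depth, v) with v the clone VAF for crypts under the branch and
an error floor elsewhere. The error floor (default 1e-3) is a modelling
necessity — a zero miscall rate would veto a branch on a single stray read —
and its value is not critical at depth 25. Clone VAF defaults to 0.5; a
per-crypt median-VAF mode is available for modestly non-clonal crypts. Ties
break toward the root, conservatively favouring shared ancestry. Variants
with no coverage anywhere go to an explicit unassigned bin, so branch lengths
always sum to the number of assigned mutations.

Node ages divide cumulative root-to-node SBS1 burden by the individual's
SBS1 rate; a branch's fission event is bounded by its parent and child node
ages. SBS1 is used because its accumulation is clock-like; the default rate
in the analysis scripts is the generator's SBS1 share of the regional clock.

## Signature attribution

Spectra are 96-channel pyrimidine-strand counts. Attribution is
multinomial-mixture EM from a uniform start (deterministic; the
log-likelihood is non-decreasing by construction and iteration stops when
both the relative log-likelihood change falls below 1e-8 and the mixing
weights settle below 1e-9). EM drains components that belong at the simplex
boundary only sublinearly, so pure-component exposures approach 100% to
working accuracy (~1e-3 in proportion, reconstruction cosine within 1e-9 of
1) rather than machine accuracy. De novo extraction is out of scope: the
catalog is given, and the pipeline's job is attribution.

The threshold ladder proceeds as follows: a first EM round on the
permitted catalog, pruning of signatures contributing <= 10%, a second round
on the survivors, and a reconstruction check at cosine 0.8 (failures are
flagged, not discarded). A signature is permitted for an individual when it
reaches >= 5% on at least one branch carrying more than 200 assigned
mutations; final per-branch signatures are the permitted ones exceeding 5%
after a final EM restricted to the permitted set — restriction by refit
rather than proportional rescaling preserves likelihood optimality. The
display threshold is applied after that reattribution; applying it before is
the other defensible order, and this package applies it after. Crypts or branches whose
combined SBS2 + SBS13 share is at least 5% are APOBEC-positive.

The packaged catalog is synthetic: peak-based approximations of SBS1, SBS2,
SBS5, SBS13, SBS17b, SBS18, SBS35, SBS40, SBS41 and SBS88 built in code
(`sbs_catalog()`), shipped as a replaceable TSV. The approximations keep each
signature's qualitative character but are deliberately more separable than
the real vectors — in particular SBS5 vs SBS40 (cosine ~0.73 here) is far
harder to resolve in real data. Real analyses should supply COSMIC v3
vectors via `load_signature_catalog()`.

## Kataegis

Mutations within 10 bases merge into one mutagenic event; candidate clusters
are maximal runs of events with adjacent gaps strictly under 10 kb, spanning
10–10,000 bases. The cluster statistic is the negative-binomial lower tail
`P = sum_{j=0}^{k} C(j+r-1, j) (1-p)^j p^r` with r = mutations − 1 — the
standard negative-binomial CDF over failures j = 0..k — k = spanned bases minus merged events, and p the *individual's*
per-base mutation rate: total passing substitutions across the patient's
crypts divided by callable genome length (default 2.9e9). Evaluation goes
through the regularized incomplete beta, exact to ~1e-14 against direct
summation. Bonferroni correction runs over the candidates tested per sample;
foci require adjusted P < 1e-4, and clusters with identical member positions
across a patient's crypts count once.

Two calibration notes. First, candidate selection conditions on closeness, so
per-crypt p-values are not super-uniform under a uniform null; the test is
calibrated in practice because p is the patient-level rate, which exceeds any
single crypt's mutation density (crypts share only part of their patient's
mutations) and makes each per-crypt test conservative. The null simulation
therefore models the study's structure — 8 crypts per patient sharing ~5%
truncal mutations — and observes zero false foci across 800 crypt tests at
the Bonferroni bound. Second, detection needs genome-scale sparsity: at
~3,000 substitutions per crypt the real genome has p ~ 1e-6 and a 6-mutation
cluster within 2 kb has raw P ~ 1e-16, while the same cluster in a desk-scale
5 Mb synthetic genome is statistically invisible. Kataegis simulations hence
draw positions at callable-genome scale; no sequence is needed.

## Stem-cell dynamics by ABC

The crypt model is Moran dynamics on `n_stem` equivalent stem cells:
replacements at total rate n x lambda, mutations Poisson along lineages at a
constant rate, a 1,000-cell crypt sampled with each surviving stem lineage
contributing equally, VAF = 0.5 x carrier-lineage fraction, and read
sampling as everywhere else. Backwards in time this is a coalescent — with j
lineages a pair merges at rate lambda j(j−1)/(n−1) — which the simulator uses
directly; it is exact for the forward model and orders of magnitude faster.
The time to the crypt's MRCA is capped at crypt founding.

Inference is plain rejection ABC (no kernel weighting): 50,000 simulations (reducible;
the package's checks use 5,000), uniform priors (defaults n_stem on {1..20},
replacement rate on [0.1, 10]/year ; the ranges are design defaults and
configurable), acceptance of the best 1% by distance, posterior
summaries of the accepted draws' true tMRCA. The distance is Euclidean
between 20-bin histograms of VAFs on (0.05, 0.55], each normalized to unit
mass; the metric itself is a design choice here, with a 1-D Wasserstein
alternative selectable. The mutation rate is fixed (in practice: the patient's
sensitivity-adjusted burden rate). Published per-crypt tMRCA summaries for this tissue require the protected
cohort; the package's own check is parameter recovery — central-interval coverage of known
tMRCA on simulated crypts.

## APOBEC sequence context

Mutated cytosines in TCA context (pyrimidine-strand normalized) are labelled
YTCA or RTCA by the base two positions 5' of the mutated C: pyrimidine
(APOBEC3A-like) versus purine (APOBEC3B-like). Enrichment follows the P-MACD
convention, `E(YTCA) = (mut_YTCA x ctx_C) / (mut_C x ctx_YTCA)`, against
background counts from ±20 bp windows around each mutation (the window
width follows the P-MACD convention and is configurable). Fisher
tests compare the YTCA:RTCA split among mutations to the split among
background motifs, one-sided in each direction; the mutations-vs-context
framing is the default of the two possible framings. Classification is
strand-symmetric by construction. The synthetic generator draws burst
channels from SBS2/SBS13 without a −2-position preference, so on synthetic
cohorts enrichment against TCA background is expected near equality of YTCA
and RTCA — the module's discriminating power is exercised by constructed
motif sets in the tests.

## Expression comparison

Single-cell matrices normalize to relative counts at scale 1e4 per cell;
group means are arithmetic over all cells including zeros, and the
small/large ratio flags division by a zero mean as infinite rather than
failing. Per-gene tests are negative binomial GLMs (log link, per-gene ML
dispersion) of raw counts on tissue, log library size, detected-feature
count and the other family genes' expression, with a two-tailed test on the
tissue coefficient and BH correction across the gene family; non-convergent
fits fall back to quasi-Poisson, flagged. Printed bulk nTPM values are
consumed as given from a packaged table; only rows whose printed ratio is
consistent with its printed means are asserted in tests.

## Problem sizes and numerical choices

The packaged checks run at these sizes, chosen to make every stochastic
assertion stable under a fixed seed: cohorts of 5 patients x 8 crypts on a
5 Mb synthetic genome at depth 25; 100,000 sensitivity simulations; EM
mixtures of 5,000 mutations; 25 ABC replicates at 5,000 simulations each; 50
mixed-model replicates; 100 patient-structured kataegis null replicates.
Degenerate inputs have defined behaviour throughout: empty variant tables
flow through the filter chain and fixture writer; zero-mass spectra are
skipped in branch attribution; rho is flagged at pooled VAF 0 or 1; a
single-crypt patient yields a one-tip tree; all-zero expression groups are
flagged at the boundary rather than tested.
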