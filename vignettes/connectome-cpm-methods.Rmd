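---
title: "Predicting phenotypes from structural connectomes: methods and design"
author: "connCPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phenotypes from structural connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Connectome-based predictive modeling (CPM) asks whether a continuous
phenotype — here a childhood-trauma sum score (CTQ-like, range 25–125) and a
social-support mean score (FSozU-like, range 1–5) — can be predicted from a
subject's structural connectome, a symmetric matrix of white-matter
streamline counts between atlas regions. `connCPM` implements the full
protocol: per-fold edge screening and selection, network-strength
summarisation, linear prediction, repeated cross-validation with per-edge
stability maps, permutation inference, and an overlap analysis between the
stable networks of two phenotypes.

# The model

Data enter as a `ConnectomeExperiment`: an E × N matrix of edge weights
(E = n(n−1)/2 for an n-node atlas; 6441 edges for the 114-node default),
with the subject table (two phenotypes; covariates age, sex, total
intracranial volume, head motion) as column data. Edges supported by fewer
than `minStreamlines` (default 3, boundary inclusive) streamlines are set
to zero per subject at load time; self-connections are never represented.

Each cross-validation fold proceeds in six steps, all statistics computed
on training subjects only:

1. **Consistency screen.** Each edge is tested against zero with a
   one-sample t-test, one-tailed in the positive direction; edges with
   p < `consistencyAlpha` (default 0.05) are retained. Zero-variance edges
   are retained when their common value is positive and excluded when all
   values are zero.
2. **Signed selection.** For each retained edge the partial Spearman
   correlation between edge weight and phenotype is computed: all variables
   are rank-transformed (average ranks for ties; the binary sex covariate
   is ranked like any other for consistency), the two rank vectors are
   residualised on the rank-transformed covariates plus intercept, and the
   residuals are correlated. Significance uses
   t = ρ·√((n−2−c)/(1−ρ²)) on n−2−c degrees of freedom. Selection takes
   the two-tailed p below `selectionAlpha` (default 0.05), split into a
   positive and a negative network by the sign of ρ; a one-tailed-per-
   direction variant is available via `selectionTails = "one"`.
3. **Network strength.** Per subject, the total number of streamlines
   (NOS) over the positive and over the negative network.
4. **Model fit.** Ordinary least squares of the phenotype on intercept,
   NOS and the raw covariates — covariates are controlled both in selection
   and in the prediction model. We include covariates as regressors rather
   than residualising the phenotype beforehand: the two choices coincide
   only in special cases, and the regressor form keeps test-set predictions
   a pure function of trained coefficients.
5. **Prediction** of held-out subjects from the trained coefficients.
6. **Evaluation**: Pearson r between true and predicted values, and mean
   absolute error (MAE, phenotype units).

**Degenerate folds.** An empty selection or constant NOS would make the
design rank-deficient; the NOS column is dropped, the model falls back to
covariates plus intercept, the fold's r is recorded as missing (excluded
from averages, counted and reported) and its MAE kept. This keeps the
repeated-CV distribution well defined on unfavourable data instead of
aborting a repetition.

# Repeated cross-validation and stability

The k-fold scheme (default k = 10) is repeated R times (default R = 100)
with fresh random balanced fold assignments, giving k·R = 1000 iterations
under the defaults. Aggregates are means over non-missing iteration values
with 95% percentile intervals over the iteration-level values; a
repetition-level variant (percentiles over the R repetition means) is
available via `ciMethod = "repetition"` — at large N both produce narrow,
similar intervals, and the iteration-level convention uses all available
resolution. Raw r values are averaged (not Fisher-z transformed), matching
the convention of reporting the mean CV correlation; the alternative is a
one-line change and was judged out of scope.

**Edge stability** is the proportion of all k·R iterations in which an edge
entered the predictive network, tracked separately per sign (an edge that
switches sign across iterations accrues stability in both maps; within one
iteration the signed sets are disjoint by construction). A leave-group-out
mode trains on the complement of each group (e.g. scanning site), one fold
per group.

# Permutation inference

Model-level significance shuffles the phenotype across subjects (covariates
and connectomes untouched, preserving their coupling), reruns the CV scheme,
and reports the proportion of permutations whose average performance
strictly exceeds the observed (higher r; lower MAE). Ties never count
against the observed model, and the plain proportion is primary — the
conservative (b+1)/(m+1) estimate is reported alongside. Per-edge stability
significance is the proportion of permutations in which the edge's permuted
stability strictly exceeds its observed stability.

Each permutation re-randomises fold assignments and, by default, runs a
single repetition of the k-fold scheme (`permRepetitions = 1`): running the
full R repetitions inside each of 1000 permutations is computationally
disproportionate. This asymmetry (coarse, noisier permuted stabilities
against finely resolved observed stabilities) makes the edge-level test
somewhat anticonservative: on null data at n = 400 with ~270 active edges
we measure roughly 10% of active edges flagged at α = 0.05 rather than 5%.
`permRepetitions` can be raised for closer symmetry; the model-level
performance p-values are well calibrated at the default (rejection rate at
the nominal 0.05 within binomial tolerance over 50 null datasets, see the
acceptance tests).

# The synthetic cohort generator

No public cohort accompanies the protocol, so the package generates data
with the statistical structure the analysis assumes; defaults emulate a
904-subject, two-site adult cohort:

* **Covariates.** Age truncated-normal on [18, 65] with location 34.04 and
  scale 12.84 (the truncated mean is ≈ 36.4; the location parameter, not
  the realised mean, is the stated 34.04), sex Bernoulli with
  P(female) = 582/904, TIV normal (1526.51, 144.61), head motion
  log-normal (right-skewed, strictly positive; meanlog log 0.15 mm,
  sdlog 0.4 — a typical mean-displacement scale).
* **Phenotypes.** A Gaussian copula couples a shared latent factor and
  transforms the margins: phenotype A is 25 + a gamma excess matched to
  mean 32.60 / SD 8.73 (clipped to [25, 125]); B is 5 − a gamma excess
  matched to mean 4.51 / SD 0.54 (clipped to [1, 5]). The latent
  correlation is calibrated once per call by deterministic root search on a
  Gauss–Hermite quadrature expression of the induced Pearson correlation,
  so the realised correlation targets −0.370 without Monte-Carlo
  calibration noise.
* **Connectomes.** A support set of `density` · E edges (default density
  0.35, a realistic sparsity for streamline connectomes at this atlas
  resolution) receives log-normal per-edge mean counts (median 20,
  sdlog 1); counts are negative-binomial with dispersion `size = 5` —
  over-dispersed, as empirical streamline counts are, with Poisson as the
  `size → ∞` limit. Planted edges add a signed term proportional to the
  subject's standardised phenotype; the per-edge gain
  √(es²/(1−es²)) · sd(baseline) targets a partial-correlation magnitude
  `effectSize` (the realised rank-based magnitude is mildly attenuated,
  ≈ 0.27 for a 0.30 target, by ranking and by the floor at zero counts).
  Planted baselines are kept at or above the log-normal median so the
  floor rarely truncates the signal. By default 7 shared edges couple
  +A/−B and 4 couple −A/+B, mirroring the inverse-sign overlap structure
  the analysis is designed to detect; per-phenotype planted set sizes are
  independently configurable.
* **Reproducibility.** All randomness flows from one master seed through
  named substreams (covariates, phenotypes, ground truth, connectome,
  folds, permutations), so components are independently reproducible and
  end-to-end runs are bit-identical under a fixed seed.

**What the generator does not emulate.** Brain-network topology
(modularity, rich-club structure, spatially correlated edges) and
site/batch effects on counts are absent; edges are conditionally
independent given the phenotypes. Passing tests therefore demonstrate the
statistical machinery — calibration, recovery, leakage-freedom — not
robustness to anatomically structured confounding.

**An interaction worth knowing.** Because the two phenotypes correlate at
−0.37, every edge planted for one phenotype is genuinely, inversely,
coupled to the other (indirect magnitude ≈ 0.37 · effectSize ≈ 0.11 at the
defaults — detectable at n = 400). A well-powered overlap analysis
therefore finds more overlapping edges than the planted shared set alone,
all with inverse sign patterns; the planted shared edges are recovered with
their planted signs. Similarly, with ~270 active edges at 40 nodes, an
uncorrected α = 0.05 edge-stability test necessarily admits on the order of
ten false edges, which bounds the attainable precision of the
significant-edge set on small synthetic universes (see the acceptance
tests; one precision clause there documents exactly this ceiling).

# Numerical choices

* Edge ordering is lexicographic over node pairs (i < j), fixed so edge
  reports are comparable across runs.
* Ranks use average ties; rows of small-range integers (the streamline
  case) are ranked by counting sort in compiled code.
* Rank residualisation solves the normal equations of the small covariate
  design (well conditioned, since rank columns have fixed scale) rather
  than a per-fold QR; an independent brute-force oracle pins both paths to
  1e-8 agreement in the tests.
* Partial correlations with zero residual variance (constant edge after
  ranking) are undefined and the edge is never selected; |ρ| = 1 maps to
  p = 0.
* Non-integer matrix entries are rejected, not rounded: streamline counts
  are counts.
* Problem sizes used by the test-suite experiments: oracle checks at
  n = 30–50 over 50 seeds; calibration at n = 400, 40 nodes, R = 5, 200
  permutations, 50 seeds; recovery at n = 400, 40 nodes, R = 20, 200
  permutations; overlap at n = 400, 40 nodes, R = 10, 200 permutations.

# Limitations

Edge selection at an uncorrected per-fold α, exactly as in the protocol,
controls no family-wise error — the permutation layer, not the selection
threshold, carries the inferential weight. The OLS prediction model is the
protocol's; no regularised learners are provided. The overlap null draws
random edge sets from the full universe by default (a flag restricts it to
consistency-masked edges, a stricter null). Anatomical labelling and
visualisation are out of scope; outputs are tabular with atlas labels.
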