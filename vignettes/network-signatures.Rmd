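---
title: "Partial-correlation networks and predictive subnetwork signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-correlation networks and predictive subnetwork signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netomicspass)
```

## The problem

Prospective clinical cohorts increasingly measure the same patients on
several platforms at once: plasma proteomics, lipidomics and acylcarnitines,
echocardiographic imaging and clinical biomarkers. Individual markers from
any one modality (NT-proBNP, E/e') carry prognostic signal, but the
modalities are strongly inter-correlated, and univariate views cannot say
which associations are direct and which are mediated by everything else that
was measured. `netomicspass` addresses this in two stages:

1. **Network inference.** All features are placed in one Gaussian graphical
   model (GGM). The sparse precision (inverse covariance) matrix
   \(\Omega\) is estimated by the graphical lasso, and each nonzero entry
   becomes a network edge weighted by the partial correlation
   \(r_{ab} = -\omega_{ab} / \sqrt{\omega_{aa}\,\omega_{bb}}\) — the
   association between features \(a\) and \(b\) after removing the linear
   effect of all other features.
2. **Supervised signature discovery.** Each network edge is converted into a
   per-subject *co-expression score* that carries the direction of the
   partial correlation, and a nearest-shrunken-centroid classifier on those
   scores selects a sparse *subnetwork signature* separating outcome groups
   (e.g. patients with versus without a secondary event). The fitted
   signature predicts class probabilities for external cohorts even when
   some features were never measured there.

## Preprocessing model

Each modality is loaded as a subjects-by-features matrix, merged over the
union of subjects, and passed through:

* **Unit harmonization** — multiplicative factors reconcile assay units
  across cohorts (e.g. natriuretic peptides reported in pmol/L vs pg/ml).
* **Completeness filtering** — features quantified in fewer than a minimum
  fraction of subjects (default 70%, the usual echocardiography rule) are
  dropped; the boundary is inclusive.
* **log2 transform** — molecular abundances (protein, lipid, acylcarnitine)
  are log2-transformed with an optional pseudo-offset (default 0). Imaging
  and clinical variables are left on their native scale by default: they
  include ratios, velocities and differences that can be legitimately
  non-positive. The set of transformed modalities is configurable.
* **Outlier flagging** — observed entries outside median ± k·MAD (MAD with
  the 1.4826 normal-consistency factor, k = 5 by default) are set to
  missing, per entry rather than per subject, so one aberrant assay value
  does not discard a patient. Features with zero MAD are skipped with a
  warning.
* **Pareto scaling** — every feature is mean-centred and divided by the
  *square root* of its sample standard deviation (n−1 denominator), computed
  over observed entries only. Pareto scaling is the standard metabolomics
  compromise between no scaling and unit-variance scaling: it damps the
  dominance of high-variance features while preserving some of the original
  variance ordering. Note that a pareto-scaled feature has variance equal to
  its original standard deviation, not 1.

A simple imputation utility (feature median, or k-nearest-subject mean) is
included as plumbing for downstream consumers that require complete data;
the network and signature stages themselves do **not** impute — they use
pairwise-complete estimation and missing-score propagation instead.

## Network inference

With missing entries, the covariance is estimated pairwise-complete: for
every feature pair, the sample covariance over the subjects where both are
observed, with means recomputed on that joint subset. Pairs with fewer than
two joint observations (no estimable covariance) are set to 0 with a
warning. A pairwise-complete matrix need not be positive semi-definite, so
eigenvalues are clipped from below at `eps = 1e-6` before optimization and
the repair is flagged.

The graphical lasso maximizes
\(\log\det\Omega - \mathrm{tr}(S\Omega) - \lambda \sum_{a\ne b}|\omega_{ab}|\).
The diagonal is **not** penalized, so independent features (S = I) give
\(\Omega = I\) at any penalty. The solver is block coordinate descent over
columns of the working covariance with a coordinate-wise lasso inner solver
(C++), warm-started along the penalty path; convergence is declared when the
mean absolute off-diagonal change per sweep falls below `tol = 1e-5`
(`max_iter = 200` sweeps). At convergence the Karush-Kuhn-Tucker conditions
hold: \(|[\Omega^{-1} - S]_{ab}| \le \lambda\) off the diagonal, with
equality on the active set — this certificate is checked in the test suite
on every path point.

The penalty is selected by extended BIC,
\[
\mathrm{eBIC}(\lambda) = n\,(\mathrm{tr}(S\Omega) - \log\det\Omega)
 + E \log n + 4\,E\,\gamma \log p,
\]
with \(E\) the number of edges and \(\gamma = 0.5\) by default (\(\gamma=0\)
is ordinary BIC; 0.5 is the customary compromise that stays consistent when
\(p\) grows with \(n\)). The default grid is 30 log-spaced penalties from
\(\lambda_{\max} = \max_{a\ne b}|S_{ab}|\) (empty network) down to
\(0.01\,\lambda_{\max}\); ties in eBIC go to the larger penalty (sparser
network). The sample size used in the eBIC is the nominal subject count;
with modest missingness the pairwise-complete counts are close to it, and a
single n keeps the criterion comparable across \(\lambda\).

## Co-expression scores and d-scores

For an edge between features \(a < b\) (canonical table order) with partial
correlation sign \(s\), the score of subject \(j\) with standardized values
\(z\) is
\[
x_{ij} = \frac{z_{aj} + s\, z_{bj}}{\sqrt{2}} .
\]
Sums capture positively coupled pairs, differences negatively coupled ones
(products and ratios on the raw scale, since the molecular values are in
logs). The \(1/\sqrt{2}\) factor is a normalization choice: independent
unit-variance nodes then give unit-variance scores, so positive and negative
edges live on one scale. A score is missing iff either node value is
missing. Edges observed in fewer than 50% of training subjects are excluded
from the signature search.

Per edge \(i\) and class \(k\), the shrunken-centroid statistics are the
class centroid \(\bar x_{ik}\), overall centroid \(\bar x_i\), pooled
within-class standard deviation \(s_i\) (denominator: observed count minus
number of classes), the offset \(s_0\) = median of the \(s_i\) (guarding
against near-zero-variance edges), \(m_k = \sqrt{1/n_k - 1/n}\), and
\[
d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k\,(s_i + s_0)},\qquad
d'_{ik} = \mathrm{sign}(d_{ik})\,\max(|d_{ik}| - \Delta,\, 0).
\]
Edges with any nonzero shrunken d-score form the signature; the shrunken
centroids are \(\bar x'_{ik} = \bar x_i + m_k (s_i + s_0)\, d'_{ik}\). Class
priors are empirical by default (`priors = "equal"` is available for
deliberately balanced designs).

## Choosing the shrinkage level

\(\Delta\) is selected on a grid of 30 equally spaced values from 0 to
\(\max_{ik}|d_{ik}|\) by stratified 10-fold cross-validation (seeded fold
shuffle, default seed 1; the fold count drops with a warning when a class is
smaller than 10).

The selection rule was a genuinely open design point. The natural rule —
take the error-minimizing \(\Delta\), ties toward the largest — has a known
failure mode on label-free data: the minimum of ~30 correlated, noisy CV
error estimates sits below the empty-classifier error almost surely, so pure
noise would routinely yield a nonempty "signature". A one-standard-error
rule does not repair this (the gap between the noise minimum and the empty
classifier regularly exceeds one fold-level standard error). The default
rule, `selection = "gated_min"`, therefore separates two questions:

1. *Is there any signal at all?* Each grid point's fold errors are compared
   with the fold errors of the empty, prior-only classifier by a paired
   one-sided t-test, Bonferroni-corrected over the grid at level 0.05. If no
   \(\Delta\) beats the empty classifier significantly, full shrinkage is
   selected and the signature is empty.
2. *If yes, how much shrinkage?* The error-minimizing \(\Delta\), ties
   broken toward the largest (sparsest classifier) — exactly the plain rule.

`"min"` and `"1se"` remain available. The phrase "penalized iteratively" in
the field's descriptions of this family of classifiers is interpreted here
as the single soft-threshold sweep of the original shrunken-centroid
construction evaluated over a \(\Delta\) grid, not as a re-fitting scheme.

## Prediction on external cohorts

New cohorts are standardized **with their own means and standard
deviations** — training moments are never applied, which keeps the method
usable across platforms with different calibration; features constant in the
new cohort become missing with a warning. For each subject, the discriminant
score per class sums over the signature edges whose two nodes are observed:
\[
\delta_k = \sum_{i \in \text{available}}
  \frac{(x_i - \bar x'_{ik})^2}{(s_i + s_0)^2} - 2\log\pi_k,
\qquad
p_k = \frac{e^{-\delta_k/2}}{\sum_l e^{-\delta_l/2}},
\]
with max-subtraction before exponentiation for numerical stability. The
same available edge set is used for every class, so no availability
rescaling is needed for the argmin/argmax comparison; subjects with fewer
than half the signature edges available are flagged `partial`, and subjects
with none fall back to the prior probabilities with flag `no_edges`.

Risk strata are quantile cuts of the outcome-class probability (tertiles by
default, ties to the lower stratum). Discrimination is summarized by the
rank (Mann-Whitney) AUC with ties counted 1/2 and a seeded stratified
bootstrap percentile 95% CI (2000 replicates by default), per edge or for
the whole signature.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws multivariate Gaussian data under a known sparse
precision matrix (banded, or random support with diagonal inflation to a
minimum eigenvalue of 0.1), splits features into the five modality blocks,
injects a class-specific mean shift of `effect`\(/\sqrt 2\) on the nodes of
randomly chosen signal edges (so the edge co-expression centroid shifts by
≈ `effect`), exponentiates the molecular blocks to a positive raw scale, and
masks entries completely at random. Defaults: 100 features (60 protein, 15
lipid, 10 acylcarnitine, 10 imaging, 5 clinical), two balanced classes of
150 subjects, banded structure of strength 0.4, 20 signal edges with unit
effect, 5% missingness — a desk-scale caricature of a post-MI multi-omics
cohort with effect sizes at the optimistic end of what strong prognostic
pairs show.

It deliberately does **not** emulate: missing-at-random structure tied to
covariates (masking is MCAR), platform batch effects, heavy-tailed or
skewed raw distributions beyond log-normality, survival times or censoring,
or medication confounding. Passing tests on this generator therefore
demonstrate correctness of the estimators and contracts, not clinical
transportability.

## Problem sizes and numerical choices

The test and acceptance workloads use: p = 50, n = 500 (banded, strength
0.4) for eBIC support recovery; a 500-edge random background network on 100
features with 20 signal edges, unit effect, n = 300 for signature recovery;
10 replicates for null calibration; n = 5000 for bivariate partial
correlation recovery; 50,000 draws for the sampler's covariance check.
Tolerances: glasso convergence 1e-5 (mean absolute off-diagonal change),
KKT certificates at 1e-3, PSD repair floor 1e-6, inverse-equivalence at
\(\lambda = 0\) within 1e-4. Degenerate inputs are handled explicitly:
constant features error during training but become missing at prediction;
zero-MAD features skip outlier flagging; degenerate quantile boundaries
collapse strata with a warning; empty signatures predict from priors.

## Known limitations

* The graphical lasso assumes joint Gaussianity after the log/pareto
  pipeline; heavy departures call for copula-style transforms that are out
  of scope here.
* Pairwise-complete covariance with very uneven missingness can be far from
  any single-population covariance; the PSD repair fixes the spectrum, not
  the bias.
* The significance gate controls nonempty-signature false positives at the
  cost of conservatism for very weak signals.
* The classifier ignores event times; subjects are treated as binary
  outcome groups, and any survival modelling must happen downstream.
* Signature covariate adjustment (age, sex) is intentionally not performed
  inside the search; adjust upstream or stratify downstream.
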