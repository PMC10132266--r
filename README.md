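# netomicspass

Partial-correlation network inference and predictive subnetwork signatures
for multi-modal clinical omics data.

## What it does, and for whom

Prospective cohorts in cardiovascular research (and beyond) measure the same
patients on several platforms: plasma proteomics, lipidomics and
acylcarnitines, echocardiographic imaging, and clinical biomarkers. The
modalities are heavily inter-correlated, so univariate marker screens cannot
distinguish direct from mediated associations, and classifiers built on raw
features transfer poorly between cohorts measured on different platforms.

`netomicspass` implements a two-stage, network-level analysis for such data:

1. **Gaussian graphical model inference.** All features enter one model. The
   sparse precision matrix Ω is estimated by the graphical LASSO

   maximize  log det Ω − tr(SΩ) − λ Σ_{a≠b} |ω_ab|

   on a pairwise-complete covariance S (missing entries tolerated, PSD
   repair by eigenvalue clipping), with the penalty λ chosen at the minimum
   of the extended BIC, eBIC(λ) = n(tr(SΩ) − log det Ω) + E log n
   + 4Eγ log p. Every nonzero ω_ab becomes a network edge with partial
   correlation r_ab = −ω_ab/√(ω_aa ω_bb).

2. **Subnetwork signature discovery and prediction.** Each edge becomes a
   per-subject co-expression score, (z_a + sign·z_b)/√2 on standardized
   (pareto-scaled) data, and a nearest-shrunken-centroid classifier on edge
   scores — d-scores d_ik = (x̄_ik − x̄_i)/(m_k(s_i + s0)), soft-thresholded
   at a cross-validated Δ — selects the sparse edge set that separates
   outcome groups. The fitted signature yields discriminant scores
   δ_k = Σ_i (x_i − x̄'_ik)²/(s_i + s0)² − 2 log π_k and class probabilities
   exp(−δ_k/2)/Σ_l exp(−δ_l/2) for new cohorts, skipping edges whose nodes
   were not measured there.

Preprocessing (unit harmonization, completeness filtering, log2 transform,
robust outlier flagging, pareto scaling), Cytoscape export (SIF + edge
attributes), per-edge and whole-signature ROC/AUC with bootstrap CIs,
tertile risk stratification, and a ground-truthed synthetic data generator
are included. See `vignettes/network-signatures.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(netomicspass)

## a ground-truthed synthetic cohort: 100 features in 5 modalities,
## 2 x 150 subjects, 99 true network edges, 20 of them carrying a
## class-specific co-expression shift, 5% missing entries
ds  <- generate_dataset(synthetic_config(seed = 1))
tab <- pareto_scale(log_transform(ds$table))

net <- infer_network(tab, gamma = 0.5)
net
#> precision_network: 100 nodes, 141 edges (density 2.85%)
#>   lambda* = 0.2538 (gamma = 0.5, n = 300)
#>   partial correlations in [-0.433, 0.061]
unlist(edge_f1(net$edges, ds$true_edges))[c("precision", "recall", "f1")]
#> precision    recall        f1
#> 0.7021277 1.0000000 0.8250000

model <- fit_signature(tab, net, ds$labels, seed = 1)
model
#> signature_model: 78 edges, classes {event_free, outcome}
#>   delta* = 0.9204 (CV error 0.137, 10 folds, seed 1)
edge_f1(model$edges, ds$signal_edges)$recall   # injected edges recovered
#> [1] 0.95

pred <- predict(model, tab)
head(pred[, c("subject_id", "prob_outcome", "predicted_class",
              "edges_used", "flag")], 3)
#>   subject_id prob_outcome predicted_class edges_used flag
#> 1       S001    0.1317716      event_free         62   ok
#> 2       S002    0.2976607      event_free         62   ok
#> 3       S003    0.3109099      event_free         73   ok

a <- auc(pred$prob_outcome, unname(ds$labels), positive = "outcome",
         seed = 1)
sprintf("AUC %.3f (95%% CI %.3f-%.3f)", a$auc, a$ci_low, a$ci_high)
#> [1] "AUC 0.943 (95% CI 0.915-0.965)"

table(stratify(pred$prob_outcome, 3), unname(ds$labels))
#>     event_free outcome
#>   1         95       5
#>   2         51      49
#>   3          4      96
```

The inferred network finds every true conditional-dependence edge at ~70%
precision; the cross-validated signature keeps 78 of 141 background edges,
recovering 19/20 injected signal edges; the resulting probabilities separate
the outcome groups cleanly into low/middle/high risk tertiles. `edges_used`
and `flag` report, per subject, how much of the signature was computable —
the prediction rule tolerates missing features by summing each subject's
discriminant over the same available edge set for every class.

A command-line front end over the same functions ships with the package
(`system.file("cli/netomicspass.R", package = "netomicspass")`) with
subcommands `preprocess`, `simulate`, `network`, `signature`, `predict`,
`evaluate`.

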