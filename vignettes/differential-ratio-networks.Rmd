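---
title: "Differential sub-networks of feature ratios: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential sub-networks of feature ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdsn)
```

## The model

A dataset D = {S_t | 1 ≤ t ≤ N_s} holds positive abundance values of m
features over labeled samples; labels are disease groups in static problems
or ordered time points in dynamic ones. `pbdsn` analyses the pairwise
feature ratios r_ij = f_i / f_j (i < j in feature order, m(m−1)/2 of them)
rather than the features themselves: a ratio cancels sample-level scaling
(dilution, loading) and directly encodes the relative balance of two
molecules, which is often the biologically regulated quantity.

For each label with n_t ≥ 3 samples a signed network G_t is built over the
ratio vertices. The edge criterion is the sample Pearson correlation
(n−1 denominator) computed over that label's samples: an edge exists when
|PCC| ≥ τ, colored red (sign +1) for PCC ≥ τ and green (−1) for PCC ≤ −τ.
An edge e of the target network is *differential* when it behaves
differently — is absent, or present with the opposite color — in at least
⌈fraction × n_comparisons⌉ comparison networks. Static problems compare
against all other groups; dynamic problems compare only against the earlier
time points, so the differential sub-network SG_t captures correlation
rewiring that is *new* at S_t and can be read as a warning signal for the
stage beginning there. Hubs of SG_t (vertices of maximal degree) are the
candidate biomarkers; their discriminative value is quantified by binary
logistic regression ROC/AUC.

Assumptions worth keeping in mind: linear (Pearson) association on the raw
ratio scale; groups large enough (n_t ≥ 3 formally, realistically ≥ 10) for
correlation estimates to be stable; strictly positive abundances after
imputation.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `tau` | 0.7 | correlation magnitude defining an edge; dimensionless in [−1,1] space. 0.7 marks strong association while tolerating estimation noise at moderate n_t. The boundary |PCC| = τ is an edge (≥, not >). |
| `fraction` | 2/3 | how many comparison networks must disagree for an edge to count as differential ("most"). `required = ceiling(fraction × n)`, so with 3 comparisons 2 must differ; with 4 earlier time points, 3. A tiny guard (1e−9) is subtracted before `ceiling` so exact integer products are not bumped up by float noise. |
| `fcThreshold` / `logBase` | 0 / 2 | pre-filter keeping features whose group-mean fold change satisfies max |log₂ FC| ≥ threshold over compared label pairs; typical analyses use 3 (expression) or 1 (metabolite concentrations). Base-2 and base-10 logs use the exact `log2`/`log10` routines and comparisons carry a 1e−9 guard, so boundary cases like an 8-fold change at threshold 3 are kept. Fold change uses arithmetic means of the (imputed, positive) raw values. |
| `compareLabels` | all | restricts fold-change comparisons to designated labels, e.g. stage-typical time points of sub-problems, instead of all pairs. |
| `k` | 5 | number of top-degree vertices retained as candidates; k = 1 isolates the hub. |

Ties in the degree ranking are broken lexicographically by vertex name. The
choice is arbitrary but fixed: determinism across runs and platforms matters
more than any particular tie order, and no principled secondary criterion
exists at the ranking stage.

## Numerical and degenerate-input choices

* Pearson values are clamped to [−1, 1] against floating-point overshoot.
* A zero-variance ratio column within a label (possible after minimum-value
  imputation of a fully missing feature×group cell) makes PCC undefined;
  such pairs contribute *no edge*, the conservative reading, rather than an
  error.
* Non-positive values (0 or negative) are treated as missing before
  imputation because ratios and log fold-changes require strictly positive
  inputs. Imputation replaces them with the minimum positive value of the
  feature within the same label group, falling back to the feature's global
  minimum positive value when a whole group is missing; a feature with no
  positive value anywhere is an error. The operation is idempotent and never
  alters an observed positive value.
* Group sizes below 3 are warned about at construction and rejected at
  network building, where PCC over fewer than 3 points is degenerate.
* Logistic fits use unpenalized IRLS (`glm`, up to 100 iterations). Under
  perfect separation the MLE diverges, but the *ordering* of fitted
  probabilities — all the ROC needs — is well defined; the result carries a
  `separation` flag. The ROC convention is a sweep over unique scores with
  midpoint tie handling, so the trapezoidal AUC equals the Mann–Whitney
  statistic. For one covariate the fitted sigmoid is monotone in the
  covariate with the sign of the slope (which equals the sign of
  cov(x, y)), so the AUC is the rank AUC of the covariate oriented by that
  sign — the test suite asserts exactly this, and the orientation caveat is
  why AUC is *not* flipped by negating a covariate: the model reorients.
* All output files are plain text with fixed number formatting (`%.17g` for
  correlations) and lexicographic edge ordering; runs with identical config
  and input are byte-identical. The run log deliberately carries no
  timestamps for the same reason.

## What the synthetic generator emulates

`generateSynthetic()` samples a log-normal latent model per label:

* every feature gets a fixed baseline log-abundance (N(4, 1), drawn once per
  dataset) plus i.i.d. log-scale noise (sd `noiseSd`, default 0.1);
* the hub pair f01, f02 shares an always-on factor u (sd 0.3) with opposite
  ±z/2 loadings of a target-only standard-normal signal z, so the hub ratio
  f01/f02 isolates z while any ratio containing only one hub member is
  dominated by u;
* partner features carry a z loading solved (on the log scale) so that the
  hub–partner ratio correlation in the target label equals
  `withinTargetPCC`; partner ratios share the denominator f02, so
  partner–partner correlations persist in *every* label and those edges are
  never differential.

The expected differential sub-network at the target is therefore a star
centered on the planted hub — the topology the hub-degree ranking is
designed to detect. In time-series mode the signal exists only at the
target time point, emulating stage onset. With `nPartners = 0` no signal is
planted anywhere (the null case).

What the generator does **not** emulate, and what passing tests therefore do
not show about real data: realistic marginal distributions or dynamic
ranges, group-level mean shifts (synthetic single-ratio AUCs sit near 0.5 by
design — the hub is visible to the network, not to a per-sample
classifier), heteroscedastic or heavy-tailed technical noise, correlated
missingness, and biological correlation structure beyond the planted star
plus the structural correlations that shared numerators/denominators induce
among overlapping ratios. Two quantitative caveats: the requested
`withinTargetPCC` is attained on the log scale and mildly attenuated by the
log-normal transform (≈0.92 realized for a requested 0.95), and borderline
structural correlations (≈0.8) between overlapping background ratios can
flicker around τ across labels, contributing a few spurious low-degree
differential edges — which is also what noisy real data would do.

## Problem sizes used in the checks

The test-suite and acceptance checks run at deliberately small scales chosen
to exercise every code path while keeping the whole suite fast: oracle
equivalence on 200 random vector pairs (n = 3–50) and 50 random network
families (≤ 8 vertices, 3–6 labels); planted-hub recovery over 20 seeds of
the reference scenario (4 groups × 20 samples, 10 features, 8 partners,
|PCC| 0.95 vs 0 background, τ = 0.7, fraction 2/3); ratio-count identities
at m = 81 and m = 17 (3240 and 136 ratios). These sizes are properties of
the checks, not limits of the implementation; the network builder is a
vectorized correlation-matrix computation and handles thousands of ratio
vertices.

## Known limitations

* Differential status is a deterministic threshold rule; no statistical
  significance is attached to an edge or a sub-network (no permutation
  null), matching the method's definition.
* Pearson correlation on the raw ratio scale is sensitive to outliers and
  to strong log-normal skew; strongly negative associations are bounded
  away from −1 on the raw scale.
* One-vs-rest logistic AUCs are in-sample unless the caller holds out data;
  no cross-validation or AUC confidence intervals are provided.
* Time-series targets are compared only against *earlier* time points, per
  the warning-signal definition; later time points never influence SG_t.
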