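---
title: "Distribution-level efficacy and specificity scoring for morphological screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-level efficacy and specificity scoring for morphological screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscore)
```

## The model

A high-content screen, after segmentation, feature extraction and
upstream normalisation, is a table with one row per cell: annotation
columns (`Metadata_` prefix) and a numeric morphology feature matrix.
`morphoscore` assumes two designated control populations span the
phenotypic axis of interest: a *reference state* (e.g. DMSO-treated
diseased cells) and a *target state* (e.g. DMSO-treated healthy cells).
Everything downstream is built from two ingredients.

**Per-feature distributional testing.** For each feature the two control
populations are compared with a two-sample Kolmogorov–Smirnov test — the
supremum of the absolute difference of the two empirical CDFs — and
p-values are Benjamini–Hochberg corrected in a single family across the
full feature space. Features with adjusted p strictly below α (default
0.05) form the on-morphology signature; the complement forms the
off-morphology signature. The partition is exhaustive and disjoint by
construction, and raising α can only grow the on-signature.

**Distribution distance.** Efficacy is measured with the exact
1-Wasserstein distance (Earth Mover's Distance) between point clouds in
the joint on-signature feature space: uniform mass `1/n` per cell,
Euclidean ground metric, solved as a discrete optimal-transport problem
over the full n × m cost matrix. The per-perturbation score is

$$\mathrm{on}(P) \;=\; \frac{\mathrm{EMD_{on}}(P,\ \mathrm{target})}
  {\mathrm{EMD_{on}}(\mathrm{reference},\ \mathrm{target})}$$

so the reference population itself scores exactly 1, the target point
set exactly 0, and populations pushed past the reference away from the
target score above 1. Because two finite samples from the same
distribution never coincide, an independent draw from the target
distribution scores slightly above 0 — 0 is an anchor, not an attainable
value. Specificity is the fraction of off-signature features that a
perturbation significantly alters (KS + BH within that perturbation's
off-feature family).

## Assumptions

- Features arrive normalised and feature-selected; the package applies
  no internal re-standardisation, so features on wildly different scales
  will dominate the Euclidean ground metric.
- Cells are exchangeable within a population: every operation is
  invariant to row order.
- Feature distributions are compared marginally during signature
  derivation; multivariate interactions enter only through the joint
  EMD. A phenotype expressed purely in feature correlations, with
  unchanged marginals, is invisible to the signature step.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | FDR threshold for both signature derivation and off-scores |
| `max_cells` | 5000 | per-population subsampling cap before the transport problem (EMD cost is quadratic in cell count); seeded uniform subsample |
| `off_comparison` | `"target"` | population the off-score tests against; `"reference"` is the documented alternative and must be chosen explicitly |
| `min_cells` (LOGO) | 5 | minimum labelled cells for a (phenotype, gene) pair to be scored |
| `n_permutations` | 5000 | label permutations behind the concordance null |
| `n_iterations` (replicate) | 10 | fresh control subsamples per reference plate × treatment |
| `control_subsample_fraction` | 0.0002 | control subsample per iteration, floored at 50 cells with a warning when the floor binds |

The off-score comparison population is a genuinely open design point:
"difference from the target state" and "difference from the reference
state" are both defensible readings of specificity. The package defaults
to the target (a specific perturbation should leave the off-features
looking the way they look in the state you are steering toward) and
exposes the alternative as an explicit argument; the CLI manifest records
the choice so results are self-describing.

## Numerical choices

- **KS p-values** use the asymptotic two-sample Kolmogorov distribution
  with the Stephens small-sample adjustment. At screen-scale populations
  the exact and asymptotic forms are indistinguishable; ties are handled
  by the ECDF definition itself, with no jitter. Features constant in
  both populations are degenerate for the test; they get statistic 0,
  p = 1 (hence the off-signature) and a warning.
- **Transport solver**: transportation simplex (u–v/MODI method) with a
  north-west-corner start, written in C++. Supplies and demands receive
  a tiny epsilon cascade (Orden's perturbation, ~1e-11) so the basis
  stays a spanning tree under the massive degeneracy of uniform weights;
  the induced cost error is orders of magnitude below the reported
  precision. Identical point multisets short-circuit to exactly 0, which
  keeps the target-scores-0 identity exact in floating point. Optimal
  cost is unique even when the plan is not, so nothing downstream ever
  depends on tie-breaking inside the solver.
- **1-D distances** (and the labelled non-default `per_feature` EMD
  mode) use the closed-form CDF integral rather than the simplex.
- **BH rejection** is `adjusted p < alpha`, strict, so the on/off
  partition matches the "below the threshold" / "at or above the
  threshold" definitions exactly.
- **Spearman** is Pearson on midranks with the t approximation; constant
  input is an error rather than a silent 0. **Kendall's W** applies the
  midrank tie correction by default with a switch to disable it, since
  published uses of W do not always state whether ties were corrected.
- **Empirical p-values** are plain directional proportions with ties
  counting as extreme; the `(1+k)/(1+N)` correction is available but off
  by default.
- **Seeding**: every randomised step draws its seed from one root seed
  through a fixed multiplicative-congruential recurrence
  (`derive_seed`), so any sub-result can be reproduced in isolation and
  all derived seeds stay below 2^31.

## The synthetic screen generator

The generator exists so that every procedure is testable with known
ground truth. It emulates exactly the distributional structure the
method consumes and nothing more:

- reference population: multivariate normal, mean 0, unit variance,
  optional shared-factor equicorrelation;
- target population: identical except a planted subset of features
  shifted by `effect_size` SD (defaults: 5 of 20 features at 3 SD, 500
  cells per group — a contrast at which per-feature recovery is
  essentially perfect, so recovery failures indicate bugs rather than
  power);
- perturbation groups with means interpolated between the two states at
  planted efficacies λ (values outside [0, 1] extrapolate), plus
  optional planted off-target shifts;
- a multi-plate variant with one effect vector per treatment shared
  across plates (magnitudes vary uniformly over 0.5–1.5 × `effect_size`,
  as treatment effect sizes do in real screens), additive plate offsets,
  and controls on every plate;
- a labelled-knockdown variant for LOGO evaluation where each gene's
  cells are a mixture of phenotype-target and reference draws, with the
  labelled fraction following a planted gradient — so efficacy rank
  should track labelled proportion, and destroying the feature values
  should decouple them.

What the generator does *not* emulate: heavy-tailed and bounded
CellProfiler feature semantics, spatial well effects, batch structure,
segmentation errors, or correlated label noise. Passing tests therefore
demonstrate correctness of the statistical machinery on clean
distributional structure, not robustness to every artifact of real
screens.

## Evaluation procedures

**Leave-one-gene-out.** For each phenotype and each gene with ≥ 5
labelled cells, all of the gene's cells are held out of the target
population before signatures are derived, and the gene's full cell set
is scored as one perturbation group. This prevents the leakage that
would let a gene trivially retrieve itself; the implementation asserts
the row-level disjointness on every pair. Genes whose derivation leaves
an empty on- or off-signature are excluded and labelled as such.

In the feature-shuffled control, feature values are permuted column-wise
across all cells and each signature's on/off membership is randomly
reassigned with sizes preserved. The signatures themselves are derived
from the *original* populations: deriving them from already-shuffled
data would leave them empty (after pooled column shuffling every subset
shares the same marginals), excluding every gene and making the control
vacuous — preserving the original signature sizes is the only reading
that yields a working null.

**Rank concordance.** Genes scored in every phenotype enter a
phenotype × gene midrank matrix; Kendall's W is compared against a null
built by permuting gene labels within each phenotype independently
(default 5,000 permutations), with the empirical p-value the proportion
of permuted W values at least as large as observed. Under independent
rankings the null W concentrates near 1/m for m phenotypes, which the
tests verify within Monte-Carlo error.

**Cross-plate replicates.** Each plate serves once as the reference
plate; per treatment and iteration, signatures are derived on that plate
from the treatment's cells (reference state) versus a fresh random
subsample of control cells (target state), and the same treatment on
every other plate is scored alongside a randomly drawn different
treatment (the non-paired null). Paired scores concentrating near 1 with
smaller spread than the non-paired distribution is the reproducibility
signature; on a no-signal screen the two distributions should be
indistinguishable. The literal control subsample fraction of 0.02% is
kept as the default but floored at 50 cells — at desk scale the floor
always binds, and the warning makes that visible.

## Problem sizes used by the test-suite

The shipped tests run the full stack at deliberately compact sizes
chosen to keep the statistical claims sharp while the whole suite
completes in a few minutes: signature recovery and anchoring identities
at 500 cells per population (20 seeds / 10 replicates), LOGO at 4
phenotypes × 10 genes × 200 cells, replicate analysis at 4 plates × 6
treatments × 60 cells × 10 iterations. These are the package's own
reference conditions; the same code paths run unchanged at screen scale,
where the `max_cells` cap bounds the transport cost.

## Known limitations

- Signature derivation treats features marginally; correlated-only
  phenotypes require a multivariate two-sample test, which is out of
  scope here.
- The exact transport solver scales quadratically in memory and worse in
  time with cell count; the subsampling cap is the intended mitigation,
  approximate solvers are not provided.
- The on-score does not say *how many* cells moved to the target state
  (a distance, not an overlap fraction).
- Quality of both signatures is bounded by the separability of the two
  control states; poorly separated states yield small on-signatures and
  a noisy normalising distance, and an empty on-signature is a hard,
  deliberate error.
- Subpopulations contribute to the scores but are not identified or
  annotated.
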