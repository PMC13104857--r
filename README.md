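# morphoscore

Signature-based efficacy and specificity scoring for single-cell
morphological screens.

## The problem

High-content imaging screens measure hundreds of morphology features for
every segmented cell, but hits are usually called from per-well mean or
median profiles. Aggregation assumes all cells respond uniformly, which
erases subpopulation structure and blunts sensitivity to subtle or
heterogeneous perturbation effects. `morphoscore` scores perturbations
directly on the *distributions* of single-cell profiles, for anyone
running image-based profiling screens (Cell Painting and similar assays)
who has two control populations that define the phenotypic axis of
interest — e.g. diseased cells (the **reference state**) and healthy
cells (the **target state**).

## The method

**1. Signature derivation.** For every morphology feature *f*, a
two-sample Kolmogorov–Smirnov test compares the reference and target
populations:

    D_f = sup_t | F_ref,f(t) − F_tgt,f(t) |

p-values are Benjamini–Hochberg corrected across the full feature space
at FDR α = 0.05. Features with adjusted p < α form the **on-morphology
signature** (the axis a successful perturbation must move cells along);
the rest form the **off-morphology signature** (features that should stay
put — movement there flags off-target activity).

**2. Scoring.** Each perturbation group *P* receives two scores:

- **on-score (efficacy)** — the Earth Mover's Distance (exact discrete
  optimal transport, uniform point masses, Euclidean ground metric over
  the joint on-signature space) between the perturbed and target cell
  populations, normalised by the reference-to-target distance:

      on(P) = EMD_on(P, target) / EMD_on(reference, target)

  1.0 ≈ still at the reference state, 0.0 ≈ complete return to the
  target state, > 1.0 ≈ pushed past the reference away from the target.

- **off-score (specificity)** — the fraction of off-signature features
  that differ significantly (KS + BH within the group's off-family)
  between the perturbed cells and the comparison population. Lower is
  more specific.

The package also ships the two evaluation procedures used to validate
such scores: a leave-one-gene-out (LOGO) analysis over phenotype-labelled
knockdown screens with label-permutation and feature-shuffling negative
controls (rank concordance via Kendall's W against a 5,000-permutation
null), and a cross-plate replicate analysis comparing paired treatments
against permuted non-paired baselines (Mann–Whitney U + BH). A synthetic
screen generator with planted ground truth makes every procedure testable
without external data.

## Worked example

```r
library(morphoscore)

# synthetic screen: 20 features, 5 truly separating the two control
# states at 3 SD, 400 cells per group, two treatments at efficacy
# lambda = 0.2 (weak) and 0.8 (strong)
screen <- generate_screen(screen_config(
  n_features = 20, n_on_features = 5, effect_size = 3,
  n_cells_per_group = 400, efficacy_grid = c(0.2, 0.8), seed = 11
))
profiles  <- screen$profiles
reference <- select_population(profiles, list(Metadata_role = "reference"))
target    <- select_population(profiles, list(Metadata_role = "target"))

sig <- derive_signatures(reference, target, alpha = 0.05)
sig
#> <signature_result> alpha = 0.05; on-signature: 5 features; off-signature: 15 features (n = 400 reference / 400 target cells)

scores <- score_screen(
  profiles, sig,
  reference_sel = list(Metadata_role = "reference"),
  target_sel    = list(Metadata_role = "target"),
  group_by = "Metadata_treatment", seed = 11
)
scores[, c("Metadata_treatment", "n_cells", "raw_emd", "on_score", "off_score")]
#>   Metadata_treatment n_cells raw_emd on_score off_score
#> 1          reference     400    6.77    1.000         0
#> 2             target     400    0.00    0.000         0
#> 3             trt_01     400    5.40    0.797         0
#> 4             trt_02     400    1.64    0.242         0
```

The signature module recovers exactly the 5 planted features. The
reference group anchors at on-score 1.000 and the target at 0.000; the
weak treatment (λ = 0.2) scores 0.797 (barely moved toward the target)
while the strong one (λ = 0.8) scores 0.242. No off-signature feature
moves, so all off-scores are 0 — the planted perturbations are perfectly
specific.

A command-line front end wraps the same functions:

```sh
./exec/morphoscore simulate --output-dir out --seed 11
./exec/morphoscore score --profiles out/profiles.csv \
    --reference-selector Metadata_role=reference \
    --target-selector Metadata_role=target --output-dir out
```

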