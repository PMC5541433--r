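---
title: "Quantifying gut-microbiota maturation: microbiota age, IMMI, reporter scores and co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gut-microbiota maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmaturity)
```

## The problem

In longitudinal animal cohorts (the motivating setting is broiler chicken
reared from hatch to slaughter at day 42, sampled under different feed
additives), the gut microbial community develops along a stereotyped
age-dependent program. A natural question is whether an intervention
*accelerates* or *delays* that program relative to an additive-free
reference group. `gutmaturity` packages the three analyses needed to answer
it, plus the supporting community statistics and a synthetic-cohort
generator that provides ground truth for every stage.

## Microbiota age and IMMI

**Model.** A regression random forest is trained on the reference group
only, regressing genus-level relative abundances against chronologic age
(days). The forest's prediction for a sample is its *microbiota age*. The
conventional defaults are used: `ntree = 5000`, `mtry = floor(p/3)`,
terminal node size 5. Because no random-forest package is available in the
target environment, the forest (bootstrap, random feature subsets,
variance-reduction splits, out-of-bag predictions, permutation importance)
is implemented in compiled code inside the package; it follows the classic
regression-forest algorithm and is exposed as `regression_forest()`.

**Feature selection.** Taxa are ranked by mean out-of-bag permutation
importance over `n_importance_iters = 100` independently seeded forests;
taxa with non-positive mean importance are flagged non-discriminatory
(the field reports "age-discriminatory taxa" without a numeric threshold,
so positivity of mean permutation importance is our operationalization).
The minimal number of top-ranked taxa is chosen by 10-fold
cross-validation over nested top-k subsets (k halving from p to 1, plus
every k ≤ 20): the selected `k*` is the smallest k whose CV error is
within `(1 + τ)` of the minimum, τ = 0.05 by default. When informative
taxa are mutually redundant — as they are in the synthetic cohorts, where
all planted trajectories are logistic in age — `k*` can legitimately be
much smaller than the number of informative taxa.

**Maturity curve and plateau.** Per group, a cubic smoothing spline
(smoothing chosen by generalized cross-validation, `smooth.spline`'s
default) is fitted of microbiota age against chronologic age and evaluated
on a daily grid. "Plateau" has no standard numeric definition; we define
`plateau_age` as the earliest grid day whose fitted value reaches
`(1 − δ)` of the curve's maximum (δ = 0.05 default) and `M*` as the fitted
value there. Reference-group samples are predicted **out-of-bag** so the
reference curve is not optimistically biased; an in-sample mode exists
(`use_oob = FALSE`) for fidelity experiments.

**IMMI** (intestinal microbiota maturation index) of a group is the
earliest grid day at which that group's fitted curve reaches the
*reference* group's `M*` — the time the group needs to reach full maturity
as defined by the additive-free animals. Curves carry the id of the age
model that produced them and `compute_immi()` refuses to compare curves
from different models. If a curve never reaches `M*` within the observed
window, the result is censored at the last observed day and flagged.

## Reporter-score pathway enrichment

KO abundances are tested per KO across treatment groups with a
tie-corrected Kruskal–Wallis test; p-values are Benjamini–Hochberg
adjusted over all tested KOs (the marker set uses adjusted p < 0.1). Each
KO's evidence becomes a Z-score through the inverse normal CDF,
`z = Φ⁻¹(1 − p_adj)`; the upper-tail probability is clipped to
`[1e-15, 1 − 1e-15]` because the transform is undefined at p ∈ {0, 1}.
A pathway with k tested member KOs scores `z_pathway = Σz / √k`, and is
standardized against the mean and SD of the same score over 1000 random
size-k KO sets drawn (without replacement within a set) from the tested KO
universe. The final `z_adjusted ≥ 1.6` (inclusive) calls a pathway
significantly perturbed. Three interpretation choices are deliberate and
documented: the score is significance-only (direction of change is not
encoded, faithful to the published construction); the background universe
is the *tested* KOs (whether untested KOs belong in the background is
unstated in the source method); and k counts only tested member KOs, not
nominal pathway size.

## Co-occurrence networks

Genus–genus association is Spearman's rank correlation (Pearson on average
ranks, so ties are exact). Edge significance uses ≥ 999 permutations of
one margin per pair with BH adjustment across the matrix. The published
method names only the correlation coefficient, so the edge and node
criteria are package defaults, all exposed as arguments: `|ρ| ≥ 0.3`,
`q ≤ 0.05`, node prevalence ≥ 0.5 and mean relative abundance ≥ 0.001.
Density is `2E/(n(n−1))`; centralization is Freeman degree centralization
`Σ(deg_max − deg_i)/((n−1)(n−2))`; the "core interaction network" is the
largest connected component (ties broken by lexicographically smallest
node set). `temporal_networks()` reproduces the pooled-then-per-period
analysis pattern and reports mean |ρ| over retained edges per network.
Compositionality-corrected correlation (renormalization resampling) is a
known fidelity gap: plain Spearman on relative abundances is used.

## Community statistics

Alpha diversity: observed richness, Shannon (natural log; a base argument
exists), Gini–Simpson, and bias-corrected Chao1
`S_obs + F₁(F₁−1)/(2(F₂+1))`, which stays defined when doubletons are
absent. Rarefaction subsamples without replacement to a fixed depth
(default 2490, the conventional depth for this design); samples below
depth are an error unless explicitly dropped. Beta diversity defaults to
Bray–Curtis (the study's phylogeny-aware distance is out of scope; any
`vegan::vegdist` metric can be named). PERMANOVA's pseudo-F and ANOSIM's R
are computed from the distance matrix directly in compiled code with
label-permutation p-values, `p = (1 + #{stat_perm ≥ stat_obs})/(1 + B)`,
B = 999 by default; both are cross-checked against `vegan` in the test
suite. Note the source article labels its ANOSIM statistic "F"; ANOSIM
defines R and that is what we report.

## The synthetic cohort generator

`generate_cohort()` emulates, at the abundance-table level (no reads, no
OTU picking):

* **age-discriminatory genera** as logistic trajectories
  `baseline + amplitude·σ(rate·(γ·t − midpoint))` — increasing or
  decreasing, clipped at zero;
* **treatment effects** as a per-group time-warp γ: γ > 1 is accelerated
  maturation, γ < 1 delayed. By construction the expected abundance at age
  t under warp γ equals the expectation at age γ·t under warp 1, so a
  group with γ = 2 that tracks a reference plateauing at day 30 should
  reach the same maturity at day 15 — the ground truth used in the
  recovery tests;
* **noise** as per-sample multiplicative log-normal perturbation
  (SD 0.3 on the log scale by default) followed by closure and multinomial
  count draws at depth 2490 per sample, mirroring rarefied count tables (a
  logistic-normal alternative was considered and not implemented);
* **competition** for the importance ranking: non-age taxa get constant
  baselines from a long-tailed log-normal.

Defaults state the simulated world once: 40 taxa of which 12 track age,
groups (control γ=1, probiotic γ=2, antibiotic γ=0.75), a dense sampling
grid every 3 days from day 1 to 42 with 6 samples per group-day (the
study-like sparse design {1, 7, 28, 42} can be requested, but plateau
detection on four support points is coarse), depth 2490. Trajectory
midpoints are drawn U(12, 24) days with rates U(0.3, 0.5)/day: this is
calibrated once so that the *fitted reference curve's 95%-of-plateau
crossing* — which is what the plateau detector measures, and which
precedes full logistic saturation — lands at about day 30. Samples are
treated as independent; real designs resample the same animals
longitudinally, and that within-subject correlation is deliberately not
modelled (flagged, not guessed). A green recovery test therefore
establishes that the pipeline inverts this stated world, not that it
reproduces any particular animal experiment.

`generate_ko_study()` plants multiplicative group shifts (default 2×) on
the member KOs of designated pathways in exactly one group over a shared
log-normal baseline. `generate_correlated_block()` plants rank dependence
through a shared latent Gaussian factor pushed through `exp()`; columns
are deliberately *not* closed to compositions because closure induces
spurious negative correlation and would break the planted independence
(this surfaced as a real bug during development — the independence
property test caught it). Negative-sign blocks use a hub pattern (first
taxon positive loading, the rest negative), matching the
"one genus negatively correlated with many" motif of interest.

## Numerical and design notes

* All randomness flows through R's RNG, including the compiled kernels, so
  a single `set.seed()`/config seed reproduces a whole pipeline run
  bit-for-bit; the pipeline driver derives per-stage seeds
  deterministically from a master seed and stamps outputs with an FNV-1a
  config hash.
* Forest predictions are averages of leaf means and therefore never leave
  the training-age range; microbiota age cannot extrapolate beyond the
  oldest reference sample.
* Degenerate inputs are contracts, not crashes: constant KOs and genera
  test at p = 1; constant taxa are excluded from networks with a record;
  a zero-variance background SD is an explicit error naming the pathway;
  an all-identical distance matrix reports a degenerate PERMANOVA with
  p = 1.
* `ko_zscore()` clips the upper-tail probability directly rather than
  forming `1 − p` after clipping p, avoiding floating-point cancellation
  near p = 1.
* The 1.6 threshold is used as printed in the source method; its
  parenthetical "90% confidence" gloss does not match Φ(1.6) ≈ 0.945 and
  is not reinterpreted.
* Pipeline configs are JSON (the guaranteed environment has no YAML
  parser); unknown blocks are rejected and failures carry the stage name.

## Known limitations

* The reference maturity curve is built from out-of-bag predictions, but
  OOB is not a fully honest generalization proxy here: the taxon ranking,
  subset selection and forest structure are all adapted to the same
  reference cohort, which inflates the reference curve by roughly 1-2
  microbiota-age units in the mature region relative to predictions on
  fresh samples from the same world. Because IMMI compares other groups'
  curves against the reference plateau value pointwise, an accelerated
  group whose curve plateaus just below the inflated reference `M*` is
  occasionally censored at the study horizon (roughly 1-2 seeds in 20 in
  the recovery simulations). The δ tolerance absorbs most but not all of
  this optimism; nesting the entire selection pipeline inside the
  out-of-sample loop would remove it at substantial cost and is not part
  of the published construction this package follows.
* No compositionality correction in the network module, no
  phylogeny-aware beta diversity, and no microbiota-for-age Z-score (MAZ)
  variant — only the curve/plateau/IMMI construction.
* IMMI comparisons inherit spline-fit uncertainty near flat plateaus; with
  few support days (e.g. the sparse {1, 7, 28, 42} design) plateau
  detection is coarse and censoring at the study horizon is common.
* The importance metric is permutation importance; impurity importance is
  not offered in this release.
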