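# gutmaturity

Tools for asking a simple question of longitudinal gut-microbiome cohorts:
**does a treatment accelerate or delay the age-dependent maturation of the
microbiota, and by how many days?** The motivating design is a
birth-to-slaughter broiler chicken trial comparing an additive-free control
group with probiotic- and antibiotic-supplemented groups, but nothing in the
package is poultry-specific: it applies to any design with genus-level (or
OTU/KO-level) feature tables, a reference group, and chronologic age per
sample.

## What it computes

**Microbiota age and IMMI.** A regression random forest (implemented in
compiled code inside the package: `ntree` trees, `mtry = ⌊p/3⌋`,
out-of-bag predictions, permutation importance) is trained on the reference
group to predict chronologic age from relative abundances. Taxa are ranked
by mean permutation importance over 100 independently seeded forests, and
the minimal top-k subset is chosen by 10-fold cross-validation. Per group, a
GCV smoothing spline of microbiota age vs chronologic age is fitted; its
plateau (earliest day reaching `(1−δ)·max`, δ = 0.05) defines full maturity
`M*` for the reference group, and the **intestinal microbiota maturation
index (IMMI)** of any group is the earliest day its curve reaches the
reference `M*` — maturation time in days, comparable across treatments.

**Reporter-score pathway enrichment.** Per-KO Kruskal–Wallis tests across
groups, BH adjustment, `z = Φ⁻¹(1 − p_adj)`, pathway score
`z_pathway = Σz/√k`, standardized against 1000 random same-size KO sets:
`z_adjusted = (z_pathway − μ_k)/σ_k`, with `z_adjusted ≥ 1.6` called
significant.

**Co-occurrence networks.** Spearman correlation with permutation p-values
and BH adjustment; signed edges at `|ρ| ≥ 0.3`, `q ≤ 0.05` (all thresholds
exposed); density `2E/(n(n−1))`, Freeman degree centralization, largest
("core") component, signed neighbor queries (e.g. which genera are
negatively correlated with *Lactobacillus*), and pooled plus per-period
network dynamics.

**Community statistics.** Observed richness, Shannon, Gini–Simpson,
bias-corrected Chao1; rarefaction without replacement (default depth 2490);
Bray–Curtis distances; PERMANOVA and ANOSIM with permutation p-values;
per-genus Kruskal–Wallis tests stratified by time point.

**Synthetic cohorts with ground truth.** `generate_cohort()` draws logistic
per-taxon age trajectories, warps time per group (γ = 2 ⇒ twice as fast),
adds log-normal noise and multinomial counting at fixed depth.
`generate_ko_study()` plants pathway-level group shifts;
`generate_correlated_block()` plants signed rank-correlation blocks. Every
generator is seeded and returns its truth labels, so each pipeline stage is
testable end to end.

## Worked example

```r
library(gutmaturity)

sim <- generate_cohort(cohort_config(seed = 7))
sim$table
#> Abundance table (counts): 40 taxa x 252 samples

res <- run_maturity_analysis(sim$table, sim$metadata, "control",
         config = age_model_config(n_trees = 500,
                                   n_importance_iters = 20, seed = 7))
res
#> Microbiota maturation analysis
#>   model: 7 taxa, OOB R2 = 0.850
#>   IMMI [control]: 29 days
#>   IMMI [probiotic]: 19 days
#>   IMMI [antibiotic]: 37 days
```

Read: the model explains 85% of age variance out-of-bag on the control
group; the control microbiota reaches full maturity at day 29 (engineered
truth 30), the probiotic-warped group (γ = 2, true maturation time 15) at
day 19, the antibiotic-warped group (γ = 0.75, truth 40) at day 37 —
accelerated and delayed maturation recovered from counts alone.

```r
ks <- generate_ko_study(ko_study_config(
        enriched_pathways = c("ko00001", "ko00002"), seed = 7))
rs <- reporter_scores(ks$table, ks$metadata$group, ks$pathways, seed = 7)
rs
#> Reporter-score enrichment: 40 pathways scored, 3 significant (>= 1.60)
head(rs$scores[order(-rs$scores$z_adjusted),
               c("pathway", "k", "z_adjusted", "significant")], 3)
#>    pathway  k z_adjusted significant
#> 2  ko00002 10   9.398099        TRUE
#> 1  ko00001 10   8.211428        TRUE
#> 20 ko00020 10   1.669898        TRUE
```

Both planted pathways are called with large margins; `ko00020` is a
borderline false positive just above the 1.6 threshold — a realistic
reminder that 1.6 is a detection threshold, not a strong-error control.

## Command line and pipeline

A CLI wrapper lives at `inst/cli/gutmaturity.R`
(`simulate | maturity | reporter | network | diversity | pipeline |
validate` subcommands), and `run_pipeline("run.json")` executes
simulate → maturity → reporter → network → diversity from a single JSON
config with a master seed, writing TSV/JSON/GraphML outputs stamped with a
config hash and per-stage seeds.

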