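# habelect

Use-versus-availability microhabitat selection and niche analysis for
quadrat surveys.

`habelect` is written for field ecologists who compare *presence*
quadrats (habitat an animal actually used) against *pseudo-absence*
quadrats (random background points sampling what the landscape offers),
with sampling points classified by season and sex into four groups
(BM, BF, NBM, NBF — breeding/non-breeding males/females). The motivating
design is a snake microhabitat survey (Stejneger's bamboo pitviper,
*Viridovipera stejnegeri*) with 13 habitat factors, each discretized into
3 ordered categories.

The package computes, per group and factor with categories
`i = 1..n` (`r_i` used quadrats, `p_i` available quadrats per category):

* **Vanderploeg selectivity** `W_i = (r_i/p_i) / Σ (r_i/p_i)` and
  **Scavia electivity** `E_i = (W_i − 1/n) / (W_i + 1/n)`, with the
  five-level rubric (strong preference / selection / random / avoidance /
  no selection, thresholds at ±0.1 and ±1);
* **Levins niche breadth** `B = 1 / Σ P_j²` per factor, aggregated over
  the 12 retained factors (aspect excluded), and **directional Levins
  overlap** `O_ik = Σ P_ij P_kj / Σ P_ij²`, symmetrized and reported in
  percent (values above 100% are legitimate and not clipped);
* a **group-label resampling null** for overlap with a 6-pair paired-t
  summary and a calibrated permutation p-value;
* the **univariate comparison battery** across sex and season:
  Mann–Whitney U (midranks, tie-corrected normal approximation) or
  one-way ANOVA after a normality/homogeneity gate for continuous
  factors, chi-square for categorical ones;
* a **synthetic survey generator** with known group preference structure
  and a pseudo-absence sampler with a minimum-distance exclusion radius,
  so the whole pipeline is testable against ground truth.

See the methods vignette (`vignettes/habitat-electivity.Rmd`) for the
model conventions and design decisions.

## Worked example

```r
library(habelect)

ds <- simulate_dataset(seed = 42)   # 92 presences + 50 pseudo-absences/season
ds
#> <habitat_dataset> 192 records (92 presence, 100 pseudo-absence), 13 factors
#>  BF  BM NBF NBM
#>  19  43  15  15

subset(selection_table(ds), group == "NBF" & factor == "altitude")
#>  group   factor category category_label r  p        Wi         Ei        class
#>    NBF altitude        1           <200 9 18 0.4782609  0.1785714    selection
#>    NBF altitude        2        200-400 6 11 0.5217391  0.2203390    selection
#>    NBF altitude        3           >400 0 21 0.0000000 -1.0000000 no_selection
```

The default generator plants a low-altitude preference in NBF, and the
electivity table recovers it: `W_i` above the no-preference point 1/3 for
the two low bins (`E_i > 0.1`, "selection") and `E_i = −1` for the unused
high-altitude bin ("no selection").

```r
group_niche_width(ds, "NBF")
#> <niche_width> NBF: aggregate B = 2.497 (mean over 12 factors)

obs <- overlap_matrix(ds)
sig <- overlap_significance(obs, resample_null(ds, 999, seed = 43))
sig
#> <overlap_report> symmetrized (mean) overlap, percent:
#>         BM     BF    NBM    NBF
#> BM  100.00  91.09  93.26  91.00
#> BF   91.09 100.00  90.42  86.32
#> NBM  93.26  90.42 100.00  90.64
#> NBF  91.00  86.32  90.64 100.00
#> paired t vs null: |t| = 1.729, df = 5, p = 0.144 (999 resamples)
```

NBF has the narrowest aggregate niche (B = 2.497 on the [1, 3] scale; the
other groups sit at 2.60–2.79) and the lowest overlaps with the other
groups, while the permutation test (`sig$perm_p = 0.13`) finds the
between-group differentiation unconvincing at these sample sizes — the
qualitative pattern this survey design typically reports.

Fed the published pairwise overlap matrices for this design, the
significance summary reproduces their printed statistics exactly:

```r
ref <- reference_overlaps()
s <- overlap_significance(ref$observed, ref$resampled)
round(c(s$mean_obs, s$sd_obs, s$mean_null, s$sd_null, s$t_stat, s$p_value), 3)
#> 79.742 18.597 85.608 14.888  0.533  0.617
```

A command-line wrapper lives at `inst/cli/habelect.R`
(`simulate | select | niche-width | niche-overlap | compare | run-all`),
and `run_pipeline()` writes the full report bundle (records, electivity
table, niche widths, overlap + null summary, comparisons, manifest, log)
deterministically from one master seed.

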