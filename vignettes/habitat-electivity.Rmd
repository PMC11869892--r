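---
title: "Electivity indices and niche analysis for use-availability quadrat surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electivity indices and niche analysis for use-availability quadrat surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habelect)
```

## The problem and the data model

habelect analyses *use versus availability* in quadrat-based microhabitat
surveys. The motivating design is a snake survey (Stejneger's bamboo
pitviper, *Viridovipera stejnegeri*): every located animal defines a
*presence* quadrat in which 13 habitat factors are measured, and a set of
random background quadrats — *pseudo-absences*, kept at least 50 m from any
same-season presence and outside unsuitable terrain — samples what the
landscape offers. Presences carry a season (breeding / non-breeding) and a
sex, giving four groups: BM, BF, NBM, NBF.

All statistics operate on factor *categories*, not raw values: each factor
is discretized into 3 ordered bins (`default_scheme()`; e.g. altitude
<200 / 200–400 / >400 m). Cut-point ownership is lower-closed, `[a, b)`,
so a value exactly on a cut point belongs to the upper bin; the published
bin labels ("<200", "200–400", ">400") do not assign the boundary, and a
single consistent rule is preferable to a per-factor convention. Custom
schemes can be supplied as YAML/JSON (`read_scheme()`), so deviating bin
definitions are a configuration, not a code change.

## Electivity: Vanderploeg $W_i$ and Scavia $E_i$

For one group and one factor with $n$ categories, let $r_i$ be the number
of used (presence) quadrats in category $i$ and $p_i$ the number of
available (pseudo-absence) quadrats in category $i$:

$$W_i = \frac{r_i/p_i}{\sum_i r_i/p_i}, \qquad
  E_i = \frac{W_i - 1/n}{W_i + 1/n}.$$

$W_i$ sums to 1 and equals $1/n$ under no preference; $E_i$ rescales it
into $[-1, (1-1/n)/(1+1/n)]$ (so at most $0.5$ for 3-level factors).
Classification follows the conventional rubric: $E_i = 1$ strong
preference, $0.1 < E_i < 1$ selection, $|E_i| < 0.1$ random, $-1 < E_i <
-0.1$ avoidance, $E_i = -1$ no selection.

Numerical conventions (all deliberate, all tested):

* The rubric's strict inequalities leave $E_i = \pm 0.1$ unassigned; we
  classify the boundary into the adjacent non-random class, and use a
  $10^{-9}$ tolerance for the $\pm 1$ endpoint checks, so classification
  is total and deterministic.
* A category never offered and never used ($p_i = r_i = 0$) is dropped
  from the sum and reported `no_data` — it carries no information and
  would make the ratio undefined. A category used but never offered
  ($r_i > 0$, $p_i = 0$) is an error: the formula implies infinite
  preference, and silently repairing it would hide an availability-sample
  defect.
* $n$ in $E_i$ is the factor's level count (`length(Wi)`), the fixed
  property of the scheme, not the count of informative categories.
* Availability is season-matched by default (the background points are
  generated per survey period); `pool_availability = TRUE` pools both
  seasons, since which convention a given study used is not always
  recoverable from its text.

The aspect factor is computed like the others but flagged
`excluded = TRUE` and left out of the niche summaries: sun-exposure
categories show at most weak electivity in this design and are
conventionally dropped downstream.

## Niche breadth and overlap

Group usage profiles $P$ (category proportions per factor) feed Levins
breadth and directional Levins overlap:

$$B = \frac{1}{\sum_j P_j^2}, \qquad
  O_{ik} = \frac{\sum_j P_{ij} P_{kj}}{\sum_j P_{ij}^2}.$$

**Resource states.** The formulas are written over generic "sampling
points $j$"; we take the states to be the factor categories, computing $B$
per factor and averaging over the 12 retained factors (arithmetic mean;
harmonic available as a sensitivity option). With 3-level factors every
per-factor $B$ — and hence the aggregate — lies in $[1, 3]$, which is the
scale on which published group breadths of this design (e.g. 2.935, 1.895)
live; treating individual quadrats as states would bound $B$ by the group
size instead. This is the one place where a convention must be inferred
from magnitudes rather than stated definitions, and it is switchable in
the code but fixed as the default.

**Symmetrization.** $O_{ik}$ is directional and can exceed 1 (a published
null matrix of this design prints 108.00%, confirming no clipping is
applied). Reported pairwise overlap is the arithmetic mean of $O_{ik}$ and
$O_{ki}$, scaled to percent; minimum, geometric (Pianka-like) and raw
directional conventions are selectable.

## The resampling null and its significance summary

`resample_null()` permutes group labels across presence records (group
sizes preserved) and recomputes the full overlap matrix.
`overlap_significance()` then compares the 6 unordered-pair overlaps,
observed versus null (elementwise mean across resamples), with a paired
t-test: $t = \bar d / (s_d/\sqrt 6)$, $df = 5$, two-sided; $|t|$ is
reported. Fed the published observed and resampled matrices
(`reference_overlaps()`), this reproduces mean $79.74 \pm 18.60$ vs
$85.61 \pm 14.89$, $|t| = 0.533$, $p = 0.617$ exactly.

**Known limitation — use the permutation p.** The 6 pair differences share
group profiles, so they are strongly correlated and the nominal $t_5$
reference is anti-conservative: under label exchangeability the paired t
rejects well above its level, while the permutation p-value (fraction of
null mean overlaps at or below the observed mean; reported whenever
`n_resamples > 1`) holds its level. Both rejection rates are recomputed at
run time by `scripts/acceptance.R` (`paired_t_type1`, `perm_type1`) and
the calibration of the permutation test is asserted in the test suite.
The paired t is retained because it is the convention this summary format
comes from; the recommended mode is `n_resamples = 999` with the
permutation p as the inferential quantity, and the single-resample mode
exists only to mirror the published single-realization design.

## Univariate group comparisons

For sex (M vs F) and season (breeding vs non-breeding) across presences:

* Continuous factors are gated: one-way ANOVA when both groups pass
  Shapiro–Wilk normality and a Levene test (Brown–Forsythe, centre =
  median) at $\alpha = 0.05$, Mann–Whitney U otherwise. Groups of fewer
  than 3 observations, or with zero variance, cannot be certified normal
  and go to Mann–Whitney.
* The Mann–Whitney U uses midranks, the standard tie correction in the
  null variance, and $Z = (U - n_1 n_2/2)/\sigma_U$ referred to the normal
  distribution, with no continuity correction by default (a switch is
  provided; which convention a given study's software used is usually
  unstated, so exact published $Z$ values are not a validation target).
  Against exhaustive enumeration of every tie-free split with
  $n_1 + n_2 \le 8$, the two-sided normal p is within 0.24 of the exact
  permutation p (the discreteness of $U$ is the binding term at such
  sizes) and within 0.17 of the exact mid-p.
* Categorical factors use Pearson's chi-square on the 2 × k group ×
  category table ($k$ after dropping categories unused by both groups;
  a zero margin is otherwise an error), with a warning when any expected
  count falls below 5.
* No multiple-testing correction is applied across the 11 variables,
  matching the analysis convention this battery reproduces.

## Preprocessing

"Extreme outlier" removal is implemented as Tukey fences at median
$\pm 3 \times$ IQR, per continuous factor and per point class, with
flagged values set to missing and every edit logged
(`$processing_log`). The optional log transform is $\ln(x+1)$ (safe at
zero distances) and is off by default: the electivity and niche statistics
bin raw values into categories and are invariant to monotone transforms,
so the transform matters only for the location tests. Missing values are
handled by listwise deletion per analysis; model-based imputation is out
of scope.

## The synthetic generator

`simulate_dataset()` exists so every stage can be validated against known
ground truth. An individual's category for each factor is drawn from
availability $\times$ preference (elementwise, renormalized), then a raw
value is drawn uniformly inside the chosen bin so the binning path is
exercised; coordinates are uniform over the extent minus rectangular
unsuitable zones; pseudo-absences are rejection-sampled (cap 10 000
attempts per point, loud failure) against the exclusion radius and zones,
drawing categories from availability alone.

Defaults were chosen once, as a realistic analogue of the motivating
survey, and are not fitted to anything: group sizes 43/19/15/15 presences
plus 50 pseudo-absences per season; uniform availability over the 3
categories of every factor (no published availability distribution exists
to copy — this is explicitly arbitrary); mild overlapping preferences for
BM/BF/NBM and a concentrated profile for NBF (low altitude, down-slope,
far from roads), mirroring the qualitative pattern such surveys report,
so the default run shows NBF with the narrowest niche.

What the generator does **not** emulate — and what passing tests therefore
do not establish about field data: spatial autocorrelation of habitat
factors, within-bin raw-value distributions (uniform here), detection
error, repeated encounters of one individual, and seasonal availability
shifts (supported via per-season availability vectors, but the default is
shared). Recovery results on synthetic data validate the *computations*,
not the field design.

Problem sizes used by the test suite were chosen to make binomial error
negligible relative to the thresholds being checked: 2 000
presences/group for the no-preference band ($|E_i| < 0.1$), 200
presences for planted-preference recovery (a 0.8-weight category implies
$E_i \approx 0.41$, four-plus standard errors above the 0.1 threshold),
and 200 replicate datasets for rate estimates (standard error about
0.015–0.03).

## Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state; `run_pipeline()` derives all stage seeds from one
master seed, and two runs with an equal configuration are byte-identical,
CSV for CSV. Output CSVs print 4 significant figures, except percent
overlaps at 2 decimal places, matching the print precision of the tables
this format follows.
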