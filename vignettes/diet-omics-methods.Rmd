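---
title: "Methods: diet-quality indices and marker association scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-quality indices and marker association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietomics)
```

## The analysis model

`dietomics` implements the cross-sectional association of diet-quality
pattern indices with circulating proteomic and metabolomic markers. For a
cohort of $N$ participants, each diet index total $S_i$ is standardized to
$z_i = (S_i - \bar S)/\mathrm{sd}(S)$ and, for every marker $y$, a separate
ordinary-least-squares model is fitted:

$$ y_{i} = \beta_0 + \beta_1 z_i + \gamma^\top c_i + \varepsilon_i $$

with covariates $c_i$ = age, sex, total energy intake (kcal/day), current
smoking, physical activity index, lipid-lowering medication,
anti-hypertensive medication, and BMI. $\hat\beta_1$ is reported as the
change in marker per SD-unit increase of the index; inference uses the t
distribution with $N - p$ degrees of freedom ($p$ = number of model columns
including the intercept — exact at any $N$, and indistinguishable from the
normal at cohort scale). Multiplicity is controlled two ways: the
Benjamini–Hochberg step-up q-value at $q \le 0.05$ defines significance,
and a Bonferroni threshold $0.05/m$ (with $m$ the platform's marker count,
e.g. 1373 proteins or 216 metabolites) flags a condensed top list.

**FDR family.** Published analyses of this design do not always state
whether FDR is computed within each diet index or pooled across the three;
the Bonferroni denominators are per platform, so the default here is the
matching choice — one BH family per (index, platform), 1373 or 216 tests.
`fdr_family = "pooled"` pools the three indices of a platform instead.

## Index definitions and scoring conventions

All three indices are built from declarative `component_spec()` lists, so
every rule below is configuration, validated structurally at load time
(`diet_index_config()` refuses a component list whose maxima do not sum to
the index maximum, or that violates the index's composition).

* **AHEI** — 11 components, 0–10 points each, maximum 110.
  Anchored-linear scoring: points interpolate between a *worst* and a
  *best* anchor and clamp outside. Reverse components (sugar-sweetened
  beverages and fruit juice, red/processed meat, trans fat, sodium) place
  the worst anchor at the high intake. The source literature for this
  index defines the component lists but the numeric anchors shipped here
  (e.g. vegetables 0 → 5 svg/d, sodium 4000 → 1500 mg/d) are **package
  defaults in the units of the generator's fields**, chosen to span a
  realistic intake range; every tested guarantee (maximum 110, minimum 0,
  monotone in intake, reverse direction) is anchor-independent.
* **AHEI alcohol** — the component-method vocabulary was extended with
  `alcohol_graded`: full points inside a sex-specific moderate window
  (defaults women 5–15, men 10–25 g/day), partial credit (2.5/10) for
  abstainers, linear decline to 0 at a heavy-consumption cut-off (25/35
  g/day). A pure 0/1 window cannot express the standard graded treatment
  of this component, and a monotone anchored ramp cannot express its
  non-monotonicity; both the window and the abstainer credit are
  configurable.
* **DASH** — 8 quintile components, 1–5 points, maximum 40 and **minimum
  8** (every component pays at least 1 point). Quintile cut-points are
  computed on the full analysis sample, not sex-stratified. Sodium,
  red/processed meat and sugar-sweetened beverages are reverse-scored
  (Q1 earns 5).
* **MDS** — 8 sex-specific quartile components scored 0–3 (red/processed
  meat reversed) plus one 0/1 moderate-alcohol window, maximum 25. The
  MUFA:SFA ratio component is sex-stratified like the others (the source
  text does not single it out, and treating one component differently
  would be surprising).

### Quantile scoring: ties and degeneracy

Cut-points are empirical quantiles (R type 7) of the stratum sample.
A value exactly equal to a cut-point falls in the **lower** bin — a
deterministic rule that needs no randomization. Zero-inflated intakes
(common for alcohol, nuts, fish; the generator's truncation at zero
deliberately produces them) can collapse adjacent cut-points; merged bins
then award the **lowest applicable bin's** points and a warning is
emitted. Reverse direction maps bin $b$ to bin $n+1-b$'s points, so
direct + reverse points are constant on tie-free data.

### FFQ validity

A dietary record is valid iff blank items < 13 **and** energy ≥ 600
kcal/day **and** energy < 4000 (women) / 4200 (men) kcal/day. Bounds are
arguments, not constants. Blank items inside otherwise-valid records are
treated as zero intake at scoring time (the standard FFQ convention);
blanks are stored as `NA`, distinguishable from a true zero.

## Marker preprocessing

Protein panels assayed in batches are processed **within batch**:
natural-log transform, then least-squares residualization on age and a
binary sex indicator, then scaling of each marker to mean 0, sample SD 1.
The phrase "age and sex adjusted values were log-transformed" is ambiguous
about order; adjusting on the log scale is the statistically conventional
reading and is what this package does (log → adjust → standardize). Sample
(n−1) SD is used throughout. Nonpositive raw values and
zero-variance markers are hard errors naming the marker (upstream QC
issues should not be silently absorbed). Metabolites are analyzed on their
delivered scale; no transform is applied by default.

The exclusion cascade in `align_tables()` reports, in order: eligible
(present in the marker matrix), excluded for invalid/missing diet,
excluded for missing covariates, analyzed — and the identity
`eligible − diet − covariates = analyzed` is asserted by tests.

## Partial Spearman correlation

"Age- and sex-adjusted Spearman correlation" is operationalized as:
rank-transform both variables (average ranks for ties), residualize each
ranked variable on the covariates by OLS, return the Pearson correlation
of the residuals. The alternative (ranking residuals) is not used; the
chosen form is exactly invariant under strictly monotone transforms of
the inputs and reduces to textbook Spearman with an empty covariate set —
both properties are tested. The heatmap ordering is average-linkage
hierarchical clustering on distance $1-\rho$; missing cells are imputed
as $\rho = 0$ with a warning. The tested artifact is the matrix and the
ordering; rendering is left to the caller (`pheatmap` works directly).

## Over-representation analysis

Given a background universe of size $N$ (default: every identifier that
maps to at least one retained set, as web ORA tools define it; an
explicit universe overrides), a selection of size $n$, and a pathway with
$K$ members, the enrichment p-value is the upper tail **including** the
observed overlap, $p = P(X \ge k)$ for hypergeometric $X$, with
enrichment ratio $(k/n)/(K/N)$ and BH-FDR across tested pathways.
Pathways are size-filtered to $[5, 2000]$ **inclusive** after restriction
to the background; the source material is internally inconsistent about
whether the boundary sizes are kept ("less than 5 excluded" vs ">5"), and
the inclusive reading was chosen and made configurable. Selected
identifiers outside the background are dropped with a warning, and the
mapped/unmapped counts are attached to the result for transparency.
Metabolite sets get descriptive annotation only (`annotate_members()`),
no test — lipid species mostly do not map to pathway databases, and a
test over a handful of mappable metabolites would be noise.

## The synthetic cohort: what it is and is not

`generate_cohort()` draws intakes and covariates from **independent**
sex-specific Gaussians truncated at zero, with defaults matching the
published summary statistics of a middle-aged, predominantly
European-ancestry community cohort (e.g. energy 1992 ± 642 kcal/day in
men, 1742 ± 566 in women; 52% women; smoking prevalence 18%). Sodium is
not reported in that summary; its defaults (2900/2500 ± 900/800 mg/day)
are package-chosen plausible values. Units follow the source table as
printed (some food groups in servings/week), with the means treated as
authoritative; quantile-based scoring is unit-free, so only the AHEI
anchor defaults care.

Planted effects are defined on the **standardized true index**: the
generator scores AHEI/DASH/MDS on the generated intakes, standardizes,
and adds $\beta \cdot z$ to the named markers plus Gaussian noise
(`noise_sd`, default 1) and optional covariate effects. Proteins are
exponentiated so the delivered matrix is strictly positive (log-normal),
with batch labels alternating deterministically (or fixed sizes, e.g.
821/1092, via `protein_batch_sizes`); metabolites are delivered on the
linear scale. `noise_sd = 0` is deliberately allowed so that exact
recovery of planted coefficients (to 1e-8) can be asserted.

What the generator does **not** emulate — and therefore what a green test
does not establish: correlation between food groups (no copula; the
indices still correlate because they share components), item-level FFQ
structure (the generator works at the food-group level the scoring
consumes), assay artifacts (limits of detection, batch drift beyond a
label, heavy tails), and confounding beyond the explicitly planted
covariate effects. Truncation at zero inflates the point mass at zero,
which is useful: it routinely exercises the merged-bin tie handling.

Null calibration and power are established by simulation in the
acceptance suite: with no planted effects, the per-test type-I error at
$\alpha = 0.05$ sits inside binomial 99% bounds over 50 seeds × 216
markers and the Bonferroni family-wise error stays ≤ 0.05 + 3 MC SE;
with 10 effects of $\beta = 0.3$ per SD at $n = 2000$, average FDR power
exceeds 90% with average false-discovery proportion ≤ 0.10, and a
$\beta = 0.10$ effect is recovered without detectable bias.

## Numerical conventions

* Quantiles: R type 7; ties to the lower bin; sample SD everywhere.
* OLS via one QR decomposition per (index, platform) design, shared
  across all markers of the scan; per-marker failures (constant markers)
  are flagged `degenerate` in the record rather than aborting the
  4000-model scan. A singular shared design is fatal by design.
* `bh_fdr()` is an explicit step-up implementation, tested for exact
  equality against a brute-force evaluation of the definition on 1000
  random vectors (and against `p.adjust(, "BH")`).
* Seeds: a single pipeline seed fans out to per-stage seeds via a
  deterministic string hash kept below $2^{31}$; identical config + seed
  gives byte-identical outputs (manifest hash equality is tested).
* Configuration files are JSON (`jsonlite`), the R-native choice among
  the formats the environment guarantees.

## Known limitations

Anchored AHEI defaults are reasonable but not canonical; users
reproducing a specific published AHEI variant must supply that variant's
anchors. The exclusion cascade assumes the marker matrix defines
eligibility. The ORA background defaults to mapped identifiers, which is
the convention of web ORA tools but not the only defensible universe —
results are sensitive to this choice, which is why the mapped/unmapped
counts are always reported. Cohort-scale published result counts (e.g.
how many of 1373 proteins pass FDR in a real cohort) depend on the real
data and are out of reach of the synthetic world by design.
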