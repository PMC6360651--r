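---
title: "Methods: the revised proximate-determinants model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the revised proximate-determinants model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bongaarts)
```

## The model and its assumptions

The package implements the multiplicative proximate-determinants model in its
revised form, in which the abortion index of the original formulation is
replaced by an index of all foetal wastage (miscarriage + abortion +
stillbirth), because direct abortion data are rarely available:

$$TFR = C_m \, C_c \, C_{fw} \, C_i \cdot TF.$$

The framework assumes that total fecundity $TF$ — fertility in the absence of
marriage patterns, contraception, postpartum infecundability and foetal
wastage — is approximately constant across populations, and that the four
determinants act independently and multiplicatively. Each index lies
nominally in $(0, 1]$: 1 means the determinant inhibits nothing, and
$(1 - C) \times 100$ is the percent of fertility it removes.

* $C_m = \sum_a m(a)\,g(a) / \sum_a g(a)$ over the seven five-year age
  groups 15–49, where $m(a)$ is the proportion of women currently in union
  (consensual unions included — the exposure concept is union, not formal
  marriage) and $g(a)$ the age-specific fertility rate.
* $C_c = 1 - 1.08\,u\,e$, with $u$ contraceptive prevalence among in-union
  women, $e$ the use-effectiveness-weighted mean over the method mix, and
  1.08 the adjustment for non-use among women who know they are sterile.
* $C_i = 20/(18.5 + i)$: the ratio of the ~20-month birth interval without
  breastfeeding or postpartum abstinence (1.5 months minimum anovulation +
  7.5 waiting to conception + 2 intrauterine mortality + 9 gestation) to the
  interval with a mean amenorrhea of $i$ months.
* $C_{fw} = TFR/(TFR + AFW)$ with $AFW = 0.4\,(1+u)\,TFW$ averted births.

The projection module holds $C_m$, $C_i$, $C_{fw}$ fixed and scales the TFR
by the contraception-index ratio, $TFR_2 = TFR_1 \cdot C_{c,2}/C_{c,1}$.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `tf` | births/woman | 15.3 | the value used throughout the bundled published stratified tables; configurable for sensitivity analysis |
| `sterility_adjustment` | — | 1.08 | the standard sterility correction; exposed as a named constant |
| `effectiveness` | — | pill 0.90, IUD 0.95, sterilization 1.00, injection 0.99, other 0.70 | the standard use-effectiveness weights; "other" covers every method outside the named four (condom, LAM, traditional) |
| `window_years` | years | 3 | retrospective exposure window for births/wastage rates; the source analysis never states its window, so the DHS convention is adopted |
| `rounding` | digits | indices 3, TFR 3 (headline 2), percents 1, projections 1 | the reporting contract; rounding happens only at the reporting layer, never inside computation |

## Numerical and design choices

* **Formula precedence.** The postpartum index is implemented as
  $20/(18.5+i)$ — the only reading consistent with the index declining as
  infecundability lengthens.
* **Out-of-range indices are flagged, not clamped.** The formulas do not
  enforce $(0,1]$ (e.g. $C_i > 1$ whenever $i < 1.5$ months, $C_c \le 0$ at
  very high $u\,e$). Such values are returned as-is with a warning of class
  `pd_index_out_of_range`, and `proximate_indices()` records them in its
  `flags` field. Silent clamping would hide data problems.
* **$g(a)$ is an all-women rate.** The marriage-index definition labels
  $g(a)$ a *marital* fertility rate but states its computation as births
  divided by *all* women in the age group; the stated computation wins. The
  label discrepancy is documented here rather than resolved.
* **Amenorrhea mean.** $i$ is the direct (weighted) mean of reported
  durations among women with a birth in the window. Women without a recent
  birth are structural missingness and are excluded, never imputed. The
  prevalence/incidence estimator used in DHS reports is a possible
  alternative but is not implemented as the default behaviour.
* **Stratum-specific prevalence.** Within strata, $C_c$ uses the stratum's
  own $u$ and method mix (required for the per-level variation seen in the
  bundled stratified tables); whether the source used stratum or national
  prevalence cannot be determined from its text.
* **Weights.** Sampling weights are supported everywhere and default to 1;
  all estimates are invariant to rescaling all weights by a constant.
* **Degenerate inputs.** An all-zero fertility schedule makes $C_m$
  undefined (error, not NaN); zero prevalence makes mean effectiveness
  undefined, and callers must set $C_c = 1$ directly — `estimate_indices()`
  does exactly that.
* **Config files** are JSON (read with jsonlite). YAML support was left out
  deliberately: the YAML parser is not part of the guaranteed runtime.

## The synthetic generator: what a green test establishes

`population_spec()` states a world — union and fertility schedules,
prevalence and method mix, amenorrhea distribution, wastage rate, covariate
shares — and `implied_indices()` computes its four indices in closed form.
`simulate_population()` then draws: age group uniform over the seven groups;
union Bernoulli$(m(a))$; method multinomial at prevalence $u$ among in-union
women; births Poisson$(g(a) \cdot \text{window})$; amenorrhea Gamma with
mean $i$ (shape 4 by default — right-skewed and positive, as duration data
are; only the mean matters to $C_i$); wastage Poisson at per-year rate
$TFW/35$. Defaults: $n = 15{,}000$ women, mirroring the scale of a national
survey round (the two emulated rounds enrolled 16,515 and 15,683 women).

`population_spec_ethiopia()` solves generator parameters so the implied
indices equal the published national (or urban/rural) index values of the
chosen round exactly: the fertility schedule is a typical sub-Saharan ASFR
shape scaled to the round's TFR, the union shape is scaled to hit $C_m$,
prevalence is solved from $C_c$ given an injectable-dominated method mix,
$i$ from $C_i$, and $TFW$ from $C_{fw}$. This calibration is prescribed by
the model's closed forms, not tuned to test outcomes.

What the generator does **not** emulate: household/cluster sampling design
and design weights, month-by-month event histories, age-dependent method
mixes, correlation between covariates (region, wealth, education and
residence are drawn independently except for the single overridden
covariate), overdispersed birth counts (a knob exists but is off by
default), and recall/reporting error. A green parameter-recovery test
therefore establishes that the estimators invert the generator's stated
world at survey scale — not that they are robust to real-survey
imperfections.

## Known limitations and one deliberate red test

* Aggregate inputs reproduce published outputs only up to the source's own
  rounding. Every one of the 44 bundled stratified rows recomposes from its
  printed indices to the printed TFR at 3 dp, and the 2016 national
  composition gives 4.14 at 2 dp; but the 2011 national composition of the
  printed indices gives 4.034 → 4.03, not the printed 4.04 (that table was
  evidently composed from unrounded internal values). The acceptance test
  asserting 4.04 is kept faithful and fails; it documents a source
  inconsistency, not a package defect.
* The bundled 2011 stratified table contains one malformed row
  (higher education: $C_i$ printed as 0, TFR as 0.00). It is carried as
  printed with `quality_flag = TRUE` and excluded from consistency checks.
* No uncertainty intervals are produced for the indices — the framework is
  deterministic given its inputs, and the source reports none.
* Real DHS recode files (CMC date arithmetic, .DTA dialects, weight
  calibration) are out of scope; the microdata mode consumes the flat
  `woman_records()` CSV schema.
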