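# bongaarts

Proximate determinants of fertility: the revised Bongaarts model in R.

## The problem

In the proximate-determinants framework, all social and economic influences on
fertility act through a small set of behavioural and biological variables. The
revised model (foetal wastage substituted for the original abortion index,
which is rarely measurable) writes the total fertility rate as a product of
four inhibiting indices applied to total fecundity TF (≈ 15.3 births per
woman):

```
TFR = Cm × Cc × Cfw × Ci × TF
```

with, in the field's standard notation:

* **Cm** = Σ m(a) g(a) / Σ g(a) — index of marriage, the fertility-weighted
  share of women in union across the seven five-year age groups 15–49;
* **Cc** = 1 − 1.08 · u · e — index of contraception, with u the prevalence
  among in-union women, e the use-effectiveness-weighted mean over the method
  mix (pill 0.90, IUD 0.95, sterilization 1.00, injection 0.99, other 0.70)
  and 1.08 the sterility adjustment;
* **Ci** = 20 / (18.5 + i) — index of postpartum infecundability, i the mean
  months of postpartum amenorrhea;
* **Cfw** = TFR / (TFR + AFW), AFW = 0.4 (1 + u) TFW — index of foetal
  wastage, with TFW the total foetal-wastage rate.

Each index is 1 when its determinant inhibits nothing; (1 − C)·100 is the
percent of fertility it removes. The package serves demographers and
reproductive-health analysts who want to (a) decompose a TFR from aggregate
index values, (b) estimate all indices from DHS-style woman-level microdata,
(c) stratify by region, wealth quintile, education and residence, and
(d) project fertility under contraceptive-prevalence scenarios
(TFR₂ = TFR₁ · Cc₂/Cc₁). Published index tables for the Ethiopia 2011/2016
DHS rounds are bundled as aggregate-mode inputs, and a synthetic population
generator with closed-form implied indices makes everything testable without
any survey data.

## Worked example

```r
library(bongaarts)

# a 15,000-woman synthetic survey calibrated to the published 2016 indices
spec <- population_spec_ethiopia("2016", n = 15000)
pop  <- simulate_population(spec, seed = 42)
est  <- estimate_indices(pop)
print(est)
#> Proximate determinants of fertility
#>  index value inhibition_pct
#>     Cm 0.657           34.3
#>     Cc 0.692           30.8
#>     Ci 0.655           34.5
#>    Cfw 0.907            9.3
#> TF = 15.3; composed TFR = 4.135 births per woman
```

The estimates recover the calibration targets (0.656, 0.693, 0.655, 0.908)
to sampling error: marriage inhibits fertility by ~34%, contraception ~31%,
postpartum infecundability ~34%, foetal wastage ~9%, composing to a TFR of
about 4.14 children per woman.

Aggregate mode needs no microdata — compose directly from printed indices:

```r
round(compose_tfr(0.656, 0.693, 0.655, 0.908, tf = 15.3), 2)
#> [1] 4.14
run_projection(data.frame(tfr1 = 4.6, u1 = 0.36, u2 = 0.55, e1 = 0.933))
#>       label tfr1   u1    e1   u2    e2     tfr2 tfr2_reported
#>  scenario 1  4.6 0.36 0.933 0.55 0.933 3.218002           3.2
```

Raising prevalence from 36% to 55% at constant use-effectiveness 0.933 takes
a baseline TFR of 4.6 down to 3.2 children per woman.

## Command line

```sh
PDF=$(Rscript -e 'cat(system.file("cli/pdf.R", package = "bongaarts"))')
Rscript $PDF simulate --year 2016 --n 15000 --seed 42 --out pop.csv
Rscript $PDF indices pop.csv --out indices.json
Rscript $PDF stratify pop.csv --by residence --out by_residence.csv
Rscript $PDF project --tfr1 4.6 --u1 0.36 --u2 0.55 --e 0.933
Rscript $PDF report pop.csv --out report/
```

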