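# drbilat

Competing-risk prognostic modelling for **metachronous bilateral breast
cancer (MBBC)** — patients whose contralateral breast develops a second
primary tumor six months or more after the first.

## The problem

An MBBC patient carries *two* sets of tumor features: T stage, N stage,
grade and ER status of the primary cancer (PBC) and of the later
contralateral cancer (CBC). Treating each bilateral pair as its own category
multiplies subtypes (9 T-pair classes, 9 N-pair classes, ...) and makes
conventional single-tumor staging inapplicable. Clinically, the *diagnosis
interval* matters: shortly after the contralateral diagnosis both tumors
carry prognostic information, while many years out the contralateral tumor's
features dominate.

`drbilat` implements an interval-time-dependent **dimensional reduction
(DR)**: each bilateral feature pair is collapsed into one weighted score

```
T_CI = w_p(t) * T_p + w_c(t) * T_c,        w_c = 1 - w_p
```

where `t` is the interval between the two diagnoses and the primary-side
weight follows an arctan law

```
w_p(t) = a * (pi/2 - arctan(b*t + c))
```

fitted per variable. The weights themselves are estimated from the data: in
overlapping interval-time windows, patients are cross-classified by (PBC
level i, CBC level j), each cell gets the area `S_ij` under its
Aalen-Johansen cumulative incidence function (CIF) of breast-cancer death on
`[0, R]` (competing risk: other-cause death), and the across-row spread
`D_p = sum_j max_{i1 != i2} |S_{i1,j} - S_{i2,j}|` is contrasted with its
column-wise counterpart `D_c` to give the raw weight
`w_p = D_p / (D_p + D_c)`.

Weighted totals are binned into DR stages by fixed cutoffs (T/N scored
1-3, stages at 1.50/2.00/2.50; grade/ER scored 1-2, one cutoff at 1.50)
and the four DR stages feed a **Fine-Gray subdistribution-hazard nomogram**
for breast-cancer-specific cumulative mortality (BCCM) at 3, 5 and 10
years, validated by a random 2:1 split, a competing-risk (Wolbers-type)
concordance index and bootstrap calibration curves. A mutant-allele tumor
heterogeneity (MATH) module covers per-lesion variant-allele-fraction
statistics: `MATH = 100 * 1.4826 * MAD(VAF) / median(VAF)`, trunk/branch
mutation fractions and the MATH-ratio-versus-interval regression.

The Fine-Gray solver is implemented in-package (Newton iterations on the
IPCW-weighted partial likelihood with suffix/prefix cumulative risk-set
sums), so cohorts of 50,000+ patients fit in well under a second; it agrees
with `survival::finegray()` + `coxph()` to machine precision, which the test
suite uses as an independent oracle.

## Worked example

No public MBBC case listing ships with the package, so the example runs on
the built-in synthetic cohort generator, whose defaults emulate a SEER-style
MBBC cohort (interval times with mean about 7 years on 0.5-25, paired
covariates with realistic concordance, two competing causes of death whose
bilateral covariate influence follows known arctan weight curves, and
independent censoring).

```r
library(drbilat)

cfg <- simulation_config(n = 20000, seed = 42)
co  <- apply_eligibility_filters(simulate_cohort(cfg))
co
#> MBBC cohort: 19482 patients (provenance: simulated(seed=42))
#>   events: 9613 censored, 5694 breast-cancer deaths, 4175 other-cause deaths

w <- fit_all_weights(co)      # interval-dependent weights, all four variables
w$t
#> Interval weight fit [t]: w_p(t) = 0.4508*(pi/2 - atan(0.2143*t + -0.5738)); RMS 0.0771

st    <- stage_cohort(co, w)                 # DR staging
sp    <- split_cohort(st, seed = 42)         # 2:1 training/validation
model <- fit_dr_nomogram(sp$training)
model
#> DR competing-risk nomogram (n = 12988)
#>   t_dr      stages 1/2/3/4 -> points 0.0/26.2/52.4/78.5
#>   n_dr      stages 1/2/3/4 -> points 0.0/33.3/66.7/100.0
#>   grade_dr  stages 1/2 -> points 0.0/19.5
#>   er_dr     stages 1/2 -> points 0.0/8.9
```

Staging one patient (T3-4 primary, T1 contralateral, interval 5.2 years) and
predicting 10-year BCCM:

```r
pat <- as.data.frame(co)[co$t_pbc == "T3-4" & co$t_cbc == "T1", ][1, ]
res <- stage_patient(pat, w)
res$dr_stage
#>     t     n grade    er
#>     2     2     2     1
predict_patient(model, res, horizon = 10)
#> $total_points
#> [1] 79.1...
#> $probability
#> [1] 0.294...
```

The weighted T total here is 1.97 -> DR stage II: a large primary tumor five
years back is softened by the small contralateral tumor, exactly the
interval-dependent trade-off the weights encode. (With the weight pair
0.37731/0.62269 at interval 5 years, scores 3 and 1 combine to
`3*0.37731 + 1*0.62269 = 1.75462`, also stage II.)

Validation on the held-out third:

```r
val <- validate_nomogram(model, sp$validation, seed = 42)
#> C-index 0.683 (95% CI 0.670-0.696)   # plus 3/5/10-year calibration tables
```

## Command line

`inst/cli/drbilat` exposes `simulate`, `filter`, `screen`, `fit-weights`,
`stage`, `fit-nomogram`, `validate`, `math` and an all-in-one `run`
subcommand driven by a JSON config (see `?pipeline_config`); `run` writes
every intermediate artifact plus a `manifest.json` recording seed and config
hash. Exit codes: 0 success, 2 configuration error, 3 stage failure.
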