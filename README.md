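# ltarisk

Latent class and latent transition models for categorical injection risk
behavior in two-arm behavioral intervention trials.

## What problem this solves

Trials of HIV/HCV prevention interventions with injection drug users
usually report one average effect on risk behavior. Risk behavior is
heterogeneous: some participants share syringes often, some share only
ancillary equipment (cookers, cotton filters, rinse water), many exhibit
almost no risk. `ltarisk` is for analysts who want to know *which kinds
of participants respond*: it classifies participants into discrete risk
profiles, links the profiles across waves with a Markov transition model,
enters trial arm as a known class, and estimates the intervention effect
within each baseline profile.

The core models:

* **Latent class analysis (LCA).** For seven 3-category indicators,
  `P(x_i) = Σ_k λ_k Π_j π_{kjx_ij}` with class proportions λ and
  class-conditional multinomial response probabilities π. EM estimation
  over collapsed response patterns, multiple starts, canonical risk
  ordering of classes; diagnostics include BIC, sample-size-adjusted
  BIC, relative entropy, average posteriors by modal class, and a
  parametric bootstrap likelihood ratio test for class enumeration.
* **Latent transition analysis (LTA).** Two waves with wave-1 class
  probabilities δ and per-arm transition matrices τ_g:
  `P(x⁽¹⁾, x⁽²⁾) = Σ_{a,b} δ_a τ_g[a,b] Π_j π_{ajx⁽¹⁾} Π_j π_{bjx⁽²⁾}`,
  with measurement ("threshold") invariance constraints over time and
  arm, full-information handling of participants missing the follow-up
  wave, ordinary and Satorra–Bentler scaled likelihood-ratio difference
  tests, and sandwich-based scaling correction factors.
* **Effects stage.** Classify-analyze regressions on modal classes:
  multinomial relative-risk ratios, the arm × baseline-class logit model
  with delta-method average marginal effects (`dy/dx`) and per-class
  odds ratios, plus attrition and trial-participation chi-square tests.
* **Synthetic cohort generator.** `default_study_config()` encodes the
  published structure of a five-city peer-education trial (class mix,
  response profiles, per-arm transitions, class-dependent dropout), so
  every stage is verifiable end-to-end by parameter recovery.

## Worked example

Simulate a trial cohort at the published values, fit the invariant
measurement LTA with arm-specific transitions, and estimate per-class
intervention effects:

```r
library(ltarisk)

sc  <- generate_cohort(default_study_config(n = 5000, seed = 7))
al  <- align_waves(recode_cohort(sc$cohort))
fit <- lta_fit(al$x1, al$x2, al$arm, K = 4, n_starts = 3, seed = 7)
fit
#> <lta_model> K=4, N=5000 (4716 with follow-up), loglik=-49990.543, params=83
#> delta: 0.323 0.230 0.202 0.245
#> tau[control]:
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.863 0.051 0.027 0.059
#> [2,] 0.682 0.201 0.066 0.050
#> [3,] 0.633 0.098 0.202 0.067
#> [4,] 0.380 0.191 0.180 0.250
#> tau[PEI]:
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.950 0.002 0.023 0.025
#> [2,] 0.628 0.265 0.073 0.034
#> [3,] 0.710 0.049 0.193 0.048
#> [4,] 0.557 0.172 0.149 0.122
```

Classes are in canonical risk order (1 = low risk, 2 = equipment
sharing, 3 = moderate-risk syringe sharing, 4 = high risk). `delta` is
the baseline class mix; row `[4,]` of each transition matrix says where
baseline high-risk participants end up at follow-up — 38% reach the
low-risk class under control versus 56% under the peer-education arm
in this n = 5000 replicate (the generating values are 37% and 53%).

```r
post  <- lta_posterior(fit, al$x1, al$x2, al$arm)
has_f <- rowSums(!is.na(al$x2)) > 0
y     <- ifelse(has_f, as.integer(post$modal_w2 == 1L), NA_integer_)
g     <- lowrisk_glm(y, al$arm, post$modal_w1)
average_marginal_effects(g)
#>   class    dydx     se   ci_lo   ci_hi       z      p    n
#> 1     1  0.0851 0.0147  0.0562  0.1139  5.7804 0.0000 1543
#> 2     2 -0.0612 0.0282 -0.1165 -0.0059 -2.1690 0.0301 1111
#> 3     3  0.0502 0.0307 -0.0100  0.1103  1.6351 0.1020  926
#> 4     4  0.1969 0.0290  0.1400  0.2537  6.7877 0.0000 1136
```

`dydx` is the average within-class change in the probability of
low-risk membership at follow-up attributable to the intervention:
here +0.20 (95% CI 0.14–0.25) for baseline high-risk participants and
+0.09 for baseline low-risk participants, with no effect in between —
the qualitative pattern the model family is designed to expose.
`arm_odds_ratios(g)` reports the same contrasts on the odds scale
(class 4: OR 2.23, i.e. 123% higher odds in this replicate).

The full pipeline (enumeration table, invariance tests, effects,
provenance-stamped JSON/CSV bundle) is one call:

```r
cfg <- pipeline_config(
  generator = default_study_config(n = 2000, cohort = "baseline"),
  K_range = 3:5, K = 4, n_starts = 10, seed = 1, out_dir = "lta-run")
report <- run_pipeline(cfg)
```

A thin CLI wrapper with `simulate` / `recode` / `lca` / `run`
subcommands is installed at `inst/cli/lta-risk`.

## Documentation

`vignettes/injection-risk-lta.Rmd` describes the models, the invariance
constraints, the generator's defaults and what they do and do not
emulate, numerical choices, and known limitations.
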