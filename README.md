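# lossaver

Does loss aversion change across adulthood, and does cortical thinning
carry part of that change? `lossaver` is an R package implementing a
complete, testable analysis chain for that question, built around a
mixed-gamble choice task and structural MRI:

- **Task design** — 128 mixed gambles drawn from a 16 × 16 grid (gains
  $10–$40 by $2, losses $5–$20 by $1), each a 50/50 chance of winning or
  losing against a certain status quo of $0; the default sampler balances
  every gain and loss level exactly.
- **Choice model** — prospect-theory subjective value
  `SV(x) = x^ρ` for gains and `−λ(−x)^ρ` for losses, with softmax
  acceptance `p = [1 + exp(−τ·SV_gamble)]⁻¹`. λ > 1 is loss aversion,
  ρ < 1 diminishing marginal utility, τ choice consistency.
- **Cleaning** — trials under 200 ms or without a response are dropped;
  participants whose choices do not become more likely with larger gains,
  smaller losses, and larger expected value are excluded.
- **Hierarchical Bayesian estimation** of (λ, ρ, τ) per subject and at
  the group level: probit-bounded parameters, non-centered normal
  hierarchy, Hamiltonian Monte Carlo with analytic gradients (compiled),
  dense-metric warmup adaptation, split-chain R-hat/ESS diagnostics, a
  per-subject maximum-likelihood oracle, and posterior predictive checks.
- **Neuroimaging side** — parcel-wise cortical-thickness tables are
  harmonized across scanners by parametric empirical-Bayes ComBat with
  age protected as a biological covariate, then aggregated into
  volume-weighted ROIs (insula, OFC, ACC, PCC, whole brain).
- **Statistics** — demographic screens (ANOVA / correlation),
  hierarchical linear-vs-quadratic age regression with nested F test and
  vertex age `−β₁/(2β₂)`, per-ROI GLMs with Holm–Bonferroni correction,
  quasi-Bayesian causal mediation (ACME/ADE with Monte-Carlo percentile
  intervals, age² as treatment), and an age-split descriptive analysis.
- **Synthetic studies** — `generate_cohort()` emits complete trial,
  thickness, and demographic tables with a known quadratic age–λ
  trajectory, linear PCC thinning, scanner offsets, and a configurable
  mediated fraction whose true ACME is available in closed form, so the
  entire chain is testable offline.

The methods vignette (`vignettes/loss-aversion-pipeline.Rmd`) documents
the model, the likelihood ridge that shapes estimation on this task, all
tunable parameters, and what the synthetic world does and does not
emulate.

## Worked example

Simulate a 60-subject study, clean it, fit the choice model, harmonize
and summarize the imaging side, and run the statistical chain:

```r
library(lossaver)

cohort  <- generate_cohort(cohort_config(n_subjects = 60, seed = 7))
cleaned <- clean_cohort(cohort$trials)
print(cleaned$report)
#> cleaning report: 51 trial(s) removed (0.6641% of trials)
#> subjects excluded: 1 of 60
#>   subject_id            reason
#> 1       s042 non_monotone_loss

fit <- fit_hierarchical(cleaned$trials, chains = 2, warmup = 1500,
                        draws = 2000, seed = 42)
print(fit)
#> hierarchical choice-model fit: 59 subjects, 2 chains x 2000 draws
#> group posterior summaries (cohort mean across subjects):
#>  parameter  mean    sd
#>     lambda 1.452 0.094
#>        rho 0.521 0.084
#>        tau 4.703 1.976
#> max split R-hat: 1.222  [FLAGGED]
```

The fit reports the posterior of the cohort-mean loss aversion (λ ≈ 1.45
± 0.09 here) and flags itself when any split-chain R-hat exceeds 1.1 —
at demo settings the flat λ–ρ–τ likelihood ridge of this task is not yet
fully mixed; longer runs (see `scripts/acceptance.R`) converge.

```r
est  <- subject_estimates(fit, cleaned$trials)
rois <- build_rois(combat_harmonize(
          cohort$thickness[cohort$thickness$qc_pass, ]))

ana <- merge(est, cohort$demographics, by = "subject_id")
ana$lambda <- ana$lambda_mean
ana$race_ethnicity <- factor(ana$race_ethnicity)
print(fit_quadratic_age(ana))
#> quadratic age regression (raw-age scale):
#>  term   estimate t_value p_value
#>   age -0.0343700   1.564   0.124
#>  age2  0.0005455   1.566   0.123
#> nested F(1, 53) = 2.451, p = 0.1234, delta R^2 = 0.0384
#> vertex age: 31.5 years
```

The quadratic trajectory shows the configured U-shape (negative age,
positive age² coefficients; minimum near age 31) — attenuated relative
to the generating coefficients because estimated λ carries measurement
noise and shrinkage, which is equally true of any real study using this
chain.

```r
mri <- merge(merge(rois, ana[, c("subject_id", "age", "lambda",
                                 "race_ethnicity")], by = "subject_id"),
             cohort$thickness[cohort$thickness$qc_pass,
                              c("subject_id", "etiv", "scanner_id")],
             by = "subject_id")
fit_thinning(mri)$slope
#> PCC thinning: -0.00915 mm/year (t = -11.36)

print(mediate(mri, n_sims = 1000, seed = 3))
#> causal mediation (quasi-Bayesian, 1000 simulations, n = 44)
#> treatment contrast: t0 = 802, t1 = 2.15e+03
#> ACME            0.8438  [-0.1716, 2.0924]  p = 0.106
#> ADE             1.0009  [-0.6901, 2.7662]  p = 0.272
#> Total           1.8447  [-0.0648, 3.6851]  p = 0.06
#> prop. mediated: 0.457
```

The ACME (indirect effect of age² through PCC thickness, here over the
interquartile treatment contrast) is positive, as built into the
generator (mediated fraction 0.5; true value ≈ 0.67 for this contrast),
but not significant at n = 44 — mediation through a mm-scale thickness
signal is intrinsically a large-sample question.

A command-line front end wraps the same steps
(`exec/lossaver simulate-design | simulate | clean | fit | harmonize |
rois | mediate | synth`).

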