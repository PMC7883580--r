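# icpseudo

Regression modelling of cumulative incidence for time-to-event data in which
the **event of interest is interval censored** (its status is only known at
examination times) while a **competing event — death — is observed exactly**.

This situation is common wherever a condition is detectable only at routine
examinations: device faults found at imaging, silent disease found at
screening. It creates two intertwined problems. First, the event time is only
known to lie in the interval between the last negative and the first positive
examination. Second, a subject can experience the event after their last
negative examination and then die before the next one, so the event is never
observed at all — the analysis must model the death hazard *after* the event
even though the event itself was missed. `icpseudo` handles both with an
**illness-death model** (states: 0 event-free, 1 event occurred, 2 dead) whose
transition-specific log cumulative hazards are restricted cubic splines in
log time (flexible parametric survival):

```
ln H_kl(t) = s_kl(x; γ_kl),   x = ln t,   kl ∈ {01, 02, 12}
```

From the fitted model, the cumulative incidence of the event of interest is

```
F01(t) = ∫₀ᵗ h01(u) S(u) du,   S(u) = exp(−H01(u) − H02(u)),
```

and **jackknife pseudo-observations** θᵢ(t) = n·θ̂(t) − (n−1)·θ̂₍₋ᵢ₎(t), built
from leave-one-out refits of the same model, turn the incompletely observed
outcome into complete data: a generalized estimating equation with identity or
log link and a sandwich variance then estimates the risk, the risk difference
and the relative risk at any landmark time, with covariate adjustment.

The maximum-likelihood machinery accommodates, in one dataset, events observed
exactly, events interval censored between examinations, and events never
observed; the likelihood core is compiled (Rcpp) and leave-one-out refits are
warm-started with a chord-Newton scheme, so the n extra fits of the jackknife
cost about one second for n = 250 on a single core.

## Worked example

Simulate a 250-subject two-arm study (the package's generator: Weibull 0→1
transition per arm, exponential competing and post-event death hazards,
80% of subjects on an examination-time observation scheme, administrative
censoring at t = 5), then estimate the cumulative incidence at t = 3 and its
association with the exposure:

```r
library(icpseudo)

cfg  <- sim_config(n = 250)
dat  <- draw_dataset(cfg, seed = 7)
recs <- observed_records(dat)

ps <- pseudo_obs(recs, eval_times = 3, m = 1)
ps
#> Parametric pseudo-observations: n = 250, eval times: 3
#>   full-sample cumulative incidence: 0.09943
#>   leave-one-out refits converged: 250/250

fit <- pseudo_gee(ps, covariates = data.frame(x = recs$x), link = "identity")
effect_estimates(fit)
#>          quantity        term estimate     se   lower upper
#> 1            risk (Intercept)   0.0736 0.0219  0.0411 0.132
#> 2 risk_difference           x   0.0445 0.0376 -0.0292 0.118

fit_rr <- pseudo_gee(ps, covariates = data.frame(x = recs$x), link = "log")
effect_estimates(fit_rr)
#>            quantity        term estimate     se   lower upper
#> 1              risk (Intercept)   0.0736 0.0219  0.0411 0.132
#> 2 log_relative_risk           x   0.4729 0.3940 -0.2993 1.245
#> 3     relative_risk           x   1.6047 0.6323  0.7413 3.473
```

Reading the output: the estimated cumulative incidence of the event of
interest by t = 3 in the unexposed arm is 7.4% (95% CI 4.1 to 13.2, interval
computed on the log scale); exposure raises the absolute risk by 4.5
percentage points (−2.9 to 11.8) and the relative risk is 1.60 (0.74 to 3.47).
The generative values for this design are a marginal cumulative incidence of
0.1235, risk difference 0.0673 and log relative risk 0.5590
(`true_values(cfg)`), so this single replication is within sampling noise.
`validate_estimates(fit)` applies the admissible-range screens (risk in (0,1),
risk difference in (−1,1), relative risk in (0.1, 10)) together with the
convergence flags.

`run_study()` wraps the whole pipeline into a simulation study (draw,
pseudo-observations under both the interval-censored method and the
exact-data comparator, GEE fits, operating characteristics: median bias,
empirical and model SE, RMSE, coverage with Wilson intervals). A command-line
front end (`inst/cli/icpseudo.R`, subcommands `fit`, `pseudo`, `regress`,
`simulate`, `study`, YAML configs) drives the same functions from a shell.

See the methods vignette (`vignettes/icpseudo-methods.Rmd`) for the model,
the likelihood with its six trajectory forms, quadrature and optimization
details, and the design choices.

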