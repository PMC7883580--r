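---
title: "Pseudo-observation regression for interval-censored competing-risks data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-observation regression for interval-censored competing-risks data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpseudo)
```

## The problem

In many follow-up studies the event of interest is only detectable at
examinations: a device fault found at routine imaging, a silent disease
picked up at screening. The event time is then *interval censored* — known
only to lie between the last negative and the first positive examination —
while a competing terminal event (death, device removal) is usually observed
exactly. Interval censoring interacts with competing risks in an awkward
way: a subject can experience the event of interest after their last
negative examination and then die before the next one, so the event is never
observed at all. Any likelihood for such data must account for these
possibly-unobserved events, which forces the model beyond cause-specific
hazards into an *illness-death* structure: state 0 (event-free), state 1
(event of interest has occurred), state 2 (dead), with transition hazards
$h_{01}, h_{02}, h_{12}$.

The target of inference is the cumulative incidence of the event of
interest,
$$F_{01}(t) = \int_0^t h_{01}(u)\, S(u)\, du, \qquad
  S(t) = \exp\{-H_{01}(t) - H_{02}(t)\},$$
and regression contrasts of it — risk differences and relative risks at a
landmark time — rather than hazard ratios. The pseudo-observation device
makes such regressions possible: replace each subject's incompletely
observed outcome indicator by the jackknife value
$$\theta_i(t) = n\,\hat\theta(t) - (n-1)\,\hat\theta_{(-i)}(t),$$
where $\hat\theta(t)$ estimates $F_{01}(t)$ on the full sample and
$\hat\theta_{(-i)}(t)$ on the sample without subject $i$, then regress the
$\theta_i$ on covariates with a generalized linear model and a sandwich
variance. Pseudo-observations require an estimator with a $\sqrt n$
convergence rate; the non-parametric estimator for interval-censored data
(Peto–Turnbull) converges at rate $n^{1/3}$, which motivates a smooth
*parametric* estimator instead.

## The flexible parametric illness-death model

Each transition's log cumulative hazard is a restricted (natural) cubic
spline in log time,
$$\ln H_{kl}(t) = s_{kl}(x;\gamma_{kl})
  = \gamma_0 + \gamma_1 x + \gamma_2 v_1(x) + \dots + \gamma_{m+1} v_m(x),
  \qquad x = \ln t,$$
with basis terms
$v_j(x) = (x-\xi_j)_+^3 - \lambda_j (x-\xi_{min})_+^3 -
(1-\lambda_j)(x-\xi_{max})_+^3$ and
$\lambda_j = (\xi_{max}-\xi_j)/(\xi_{max}-\xi_{min})$. This choice of
$\lambda_j$ is the unique one making each $v_j$ a natural-spline term
(twice continuously differentiable, linear outside the boundary knots); the
package implements the exact analytic derivative of this basis and verifies
it against finite differences in the test suite. With no internal knots the
basis is $[1, x]$ and $\gamma = (\ln k, b)$ recovers the Weibull family
$H(t) = k t^b$ (scale $k$, shape $b$) exactly — the test suite pins this
reduction down to $10^{-10}$ and it fixes the Weibull parameter convention
used throughout, including the simulation generator.

The hazard follows as $h(t) = t^{-1} s'(x) e^{s(x)}$. Nothing constrains
$s'$ to be positive: a fitted spline can be locally decreasing, giving a
negative hazard. Following flexible-parametric practice the optimizer does
not constrain this; `trans_hazard()` warns when it happens, and the
likelihood returns $-\infty$ whenever a *density* would be required at a
point with non-positive hazard (an exactly observed event or death), or
whenever a total contribution fails to be positive.

### Knots

Knot counts in this package always refer to *internal* knots `m`; boundary
knots are additional. (Descriptions of spline models in the applied
literature are ambiguous on this point, so the convention is stated here
once and used everywhere.) `place_knots()` puts boundary knots at the range
and internal knots at equally spaced quantiles of log event-time proxies;
for interval-censored events the proxies are interval midpoints, matching
the midpoint-based initialization below. `default_specs()` derives
per-transition proxies (exact times and midpoints for $0\!\to\!1$, deaths
without prior event for $0\!\to\!2$, deaths after the event for
$1\!\to\!2$) and falls back to wider pools — all deaths, then all
observation times, then fewer knots — when a transition has too few
distinct times. Leave-one-out refits always reuse the full-sample knots, so
the jackknife perturbs only the coefficients.

## Likelihood

The observed data per subject are $(l_1, t_1, d_1, \text{exact}, t_2,
d_2)$: last negative examination, observation time of the event of
interest, its indicator and exact/interval flag, and the exactly observed
competing-event time and indicator. Writing
$E(u, t_2) = \exp\{-(H_{12}(t_2) - H_{12}(u))\}$, the three contribution
forms are

* exact event at $t_1$:
  $L_i = S(t_1)\, h_{01}(t_1)\, E(t_1, t_2)\, h_{12}(t_2)^{d_2}$;
* no observed event:
  $L_i = S(t_2)\, h_{02}(t_2)^{d_2} + \int_{l_1}^{t_2} S(u) h_{01}(u)
  E(u, t_2)\, h_{12}(t_2)^{d_2}\, du$, the integral carrying the
  possibility of an unobserved event after $l_1$;
* interval-censored event in $(l_1, t_1]$: the same integral over
  $(l_1, t_1)$.

Each form splits in two by $d_2$ (death versus censoring), giving six
trajectories; the convention $0^0 = 1$ applies to the $d_2$ exponent.
Events detected at the terminal examination ($t_1 = t_2$) are accepted, the
integral simply running over $(l_1, t_1)$. The test suite validates all six
forms two ways: against closed-form exponential integrals, and against
trajectory-bin frequencies from $10^6$ simulated paths of a fixed
exponential illness-death process observed on a fixed examination grid.

### Quadrature

Likelihood integrals use 64-node Gauss–Legendre quadrature (node count
configurable) after the substitution $u = a + (b-a)w^2$, which avoids
evaluating the integrand at the endpoints; when $l_1 = 0$ and the 0→1
hazard has a Weibull-type singularity $u^{b-1}$ with $b<1$, the
substitution also damps the singularity. For the cumulative incidence
itself, where accuracy to near machine precision is wanted, the map
exponent adapts to the fitted tail slope $\gamma_1$ (below the lowest knot
the spline is exactly linear, so $h \sim u^{\gamma_1 - 1}$ there): with
$u = t w^p$ and $p \ge 2/\gamma_1$ the transformed integrand vanishes at
the origin and 64 nodes deliver ~$10^{-12}$ absolute accuracy, checked in
the tests by node doubling and against independent adaptive quadrature.

### Maximization

The log-likelihood is maximized over the stacked coefficients
$(\gamma_{01}, \gamma_{02}, \gamma_{12})$ by BFGS with *analytic*
gradients (derived term by term from the contribution forms and verified
against finite differences), followed by a chord-Newton polish with a
finite-difference Hessian of the analytic gradient that drives the gradient
sup-norm below $10^{-8}$. The polish matters for the jackknife: a
relative-change stopping rule alone can leave two runs at slightly
different points of a flat valley, and the pseudo-observation magnifies any
such discrepancy by $n-1$. When no likelihood term involves the 1→2
transition — purely right-censored cause-specific data, where follow-up
ends at the first event — those coefficients are automatically excluded
from the optimization.

Leave-one-out refits warm-start at the full-sample coefficients and reuse
its factored Hessian (chord Newton), falling back to the full BFGS path if
the iteration stalls; a test on a 30-subject dataset confirms warm and cold
starts agree in the estimated cumulative incidence to well below $10^{-6}$.
In very small subsamples a transition can degenerate — e.g. removing one of
two observed state-1 deaths lets the 1→2 likelihood drift toward a
boundary. The affected refit is then flagged non-converged, which (per the
validity rules below) invalidates the replication; the cumulative incidence
itself, which does not involve $H_{12}$, remains stable in such cases.

### Initial values

Starting coefficients come from a midpoint scheme: (i) fit the 0→1
transition alone, treating interval-censored events as exact at their
interval midpoints; (ii) for each subject without an observed event,
compute the probability of an unobserved event between $l_1$ and $t_2$
from that fit — implemented as the conditional probability
$(\hat S(l_1) - \hat S(t_2)) / \hat S(l_1)$ given event-free status at
$l_1$, with the unconditional difference available via `prob = "marginal"`
(the choice only affects starting values); (iii) assign unobserved events
by per-subject Bernoulli draws (deterministic given the seed) at the
midpoint of $(l_1, t_2)$; (iv) fit 0→2 and 1→2 on the augmented data, the
latter with delayed entry at the (imputed) event time, i.e. conditioning
each contribution on survival in state 1 to the entry time. Sub-fit
failures fall back to per-transition exponential rates. On a simulated
dataset of 500 subjects this initializer reaches the optimum in fewer
likelihood evaluations than naive unit-exponential starts (asserted in the
tests).

## Pseudo-observations and regression

`pseudo_obs()` returns the full-sample estimate, the $n$ leave-one-out
estimates and the pseudo-observations; the jackknife identity is exact by
construction and pseudo-values are deliberately *not* clipped to $[0,1]$ —
values outside the unit interval are a normal feature of jackknife
pseudo-data. `pseudo_gee()` solves the estimating equation
$$\sum_i \left(\partial_\beta\, g^{-1}(\beta^\top Z_i)\right)^\top V_i^{-1}
  \left(\theta_i - g^{-1}(\beta^\top Z_i)\right) = 0$$
with $g(x)=x$ (risk difference) or $g(x)=\ln x$ (relative risk), an
independence working covariance (for a single evaluation time the scalar
working variance cancels from the equation), Fisher scoring with step
halving for the log link, and the sandwich variance
$A^{-1} B A^{-\top}$ with the meat clustered on subjects. Two small-sample
conventions for the meat are available — none (default) and an HC1-type
factor $n/(n-p)$ — because published simulation summaries do not pin down
which is in use; at $n = 250$ the difference is under half a percent of the
standard error. Confidence intervals use the normal quantile 1.96: risk on
the log scale via the delta method, $\exp(\ln\hat\theta \pm 1.96\,
SE(\ln\hat\theta))$, to respect the asymmetry of the risk scale; risk
differences symmetric on the natural scale; relative risks symmetric on the
log scale and exponentiated.

Estimates are screened by the validity rules: any non-convergence (full
sample or any leave-one-out refit) or an estimate outside its admissible
range — cumulative incidence outside $(0,1)$, risk difference outside
$(-1,1)$, relative risk outside $(10^{-1}, 10)$ — marks the result invalid.
The simulation harness excludes invalid replications per estimand and
reports how many survive.

### The marginal cumulative incidence: plug-in versus pseudo-mean

For covariate effects (risk difference, relative risk) the pseudo-value GEE
is the method — there is no plug-in alternative. For the *marginal*
cumulative incidence there are two natural point estimates: the full-sample
maximum-likelihood plug-in $\hat\theta(t)$, and the intercept-only GEE
solution, which equals the mean pseudo-value $n\hat\theta -
(n-1)\overline{\hat\theta_{(-i)}}$, i.e. the jackknife bias-corrected
estimate. For smooth functionals these differ by $O(1/n)$, but the
jackknife correction is fragile: a single highly influential observation —
typically an exactly observed event very early in follow-up, where it alone
informs the spline's lower tail — can carry a pseudo-value of 10 or more
and move the mean far from $\hat\theta$, while remaining inside the
admissible range $(0,1)$ that the validity filters check. In simulation at
$n = 250$ this inflates the between-replication spread of the pseudo-mean
well above that of the plug-in (and above the model-based SE, which both
agree with), without any corresponding bias benefit. `run_study()`
therefore reports the plug-in as the marginal cumulative incidence estimate
by default, keeping the pseudo-value sandwich SE for inference;
`cip_estimate = "pseudo_mean"` switches to the bias-corrected version.

## The simulation generator

`draw_dataset()` emulates a two-arm observational follow-up with a
deterministic half/half binary exposure (first half of the sample exposed —
the exposure is non-random by design, so nothing is lost by fixing the
order):

* $T_{01} \sim$ Weibull with $H_{01}(t) = k t^b$, $k = 0.06, b = 0.5$
  unexposed and $k = 0.12, b = 0.4$ exposed, drawn by inverse transform;
* $T_{02} \sim$ Exp(0.1); whichever of $T_{01}, T_{02}$ comes first before
  the administrative horizon $t = 5$ determines the first transition;
* after an event of interest, death follows at $T_{01} + T_{12}$ with
  $T_{12} \sim$ Exp(0.4), censored at 5;
* each subject's observation scheme is interval censored with probability
  $p_{ic} = 0.8$, otherwise the event time is observed exactly;
* examination times advance from $e_0 = 0$ by increments
  $\delta \sim N(1, 0.2)$ until the event has been detected or follow-up
  has ended. A normal increment is negative with probability ~1.3%; such
  draws are redrawn, which preserves the nominal mean and variance to a
  good approximation while guaranteeing a valid grid;
* events with no examination between occurrence and death/censoring are
  *unobserved*: recorded with `d1 = 0`, exactly as a real registry would
  record them. Latent times are retained alongside the observed record so
  the "exact" comparator — the right-censored cause-specific data one
  would have without interval censoring — can be built from the same draw.

What the generator does *not* emulate: informative examination schedules
(examinations independent of risk is an assumption of the method itself),
interval censoring of the competing event (out of scope of the model),
covariate-dependent censoring, and heterogeneous per-subject examination
intensities. Passing simulation tests therefore demonstrate correctness
under independent inspection, not robustness to informative inspection.

True values of the estimands are computed by deterministic quadrature of
$F_{01}$ per arm (marginal cumulative incidence 0.1235, risk difference
0.0673, log relative risk 0.5590 at $t = 3$) rather than by brute-force
simulation of $10^8$ subjects; the generator itself provides the Monte
Carlo cross-check (a $10^6$-draw comparison of event fractions against
quadrature is part of the test suite).

## Study harness and problem sizes

`run_study()` replicates the full pipeline — draw, pseudo-observations
under both the interval-censored and the exact comparator method, three GEE
fits (marginal cumulative incidence via the intercept-only identity-link
model, risk difference via the identity link, log relative risk via the log
link) — and summarizes median bias, empirical SE (SD of estimates),
relative empirical SE against the exact method, mean model SE, RMSE, and
95% interval coverage with a Wilson score interval.

The package's own validation runs the study at 200 replications of
$n = 250$ with one internal knot per transition — a size chosen so the full
suite executes in minutes on a single core thanks to the compiled
likelihood and warm-started jackknife, while keeping the Monte Carlo error
of an empirical SE near 5% of its value. The number of internal knots for
simulation fits is a free choice (published descriptions do not state one);
`m = 1` is the default and `m` is configurable throughout. A sensitivity
run at `m = 2` shows the exact-method characteristics essentially
unchanged, while the interval-censored method loses more replications to
non-convergence and its jackknife becomes markedly more fragile (more
spline flexibility means single observations can dominate the sparsely
informed parts of the curve) — a further reason to keep the default spline
small at this event count.

## Known limitations

* The competing event must be exactly observed; interval-censored competing
  events are structurally outside this likelihood.
* The illness-death model is marginal: covariates enter only through the
  pseudo-observation regression, so the leave-one-out estimator ignores
  covariate information when refitting, exactly as intended by the method,
  but covariate-specific baseline shapes are not modelled.
* Left truncation at study entry is not supported (delayed entry is used
  internally only for the 1→2 initial-value fit).
* With very few transitions of a given type the unpenalized likelihood can
  drift toward boundary configurations in leave-one-out subsamples; this is
  detected and flagged rather than prevented.
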