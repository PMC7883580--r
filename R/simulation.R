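#' Simulation configuration
#'
#' Generative parameters for the illness-death simulation: a non-random
#' binary exposure (first half of the sample exposed), a Weibull 0->1
#' transition per arm with cumulative hazard \eqn{H_{01}(t) = k t^b} (scale
#' \eqn{k}, shape \eqn{b}), exponential 0->2 and 1->2 transitions,
#' administrative censoring at `censor_time`, and an examination-time
#' observation scheme: each subject is interval censored with probability
#' `p_ic`, examinations advance by increments \eqn{\delta \sim N(\Delta,
#' \sigma^2)} (redrawn until positive) from time 0 until the event of
#' interest has been detected or follow-up has ended.
#'
#' @param n sample size.
#' @param k01,b01 length-2 Weibull scale and shape for the 0->1 transition,
#'   `(unexposed, exposed)`.
#' @param lambda02 exponential intensity of the 0->2 transition.
#' @param lambda12 exponential intensity of the 1->2 transition.
#' @param censor_time administrative censoring horizon.
#' @param p_ic probability a subject's event-of-interest observation scheme
#'   is interval censored (otherwise the event time is observed exactly).
#' @param delta_mean,delta_var mean and variance of the examination
#'   increments.
#' @param eval_time evaluation time for the cumulative incidence.
#' @param m internal knots per transition used by the analysis.
#' @param nodes quadrature node count used by the analysis.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n = 250L, k01 = c(0.06, 0.12), b01 = c(0.5, 0.4),
                       lambda02 = 0.1, lambda12 = 0.4, censor_time = 5,
                       p_ic = 0.8, delta_mean = 1, delta_var = 0.2,
                       eval_time = 3, m = 1L, nodes = 64L) {
  stopifnot(n >= 2, all(k01 > 0), all(b01 > 0), lambda02 > 0, lambda12 > 0,
            censor_time > 0, p_ic >= 0, p_ic <= 1, delta_mean > 0,
            delta_var >= 0, eval_time > 0)
  structure(list(n = as.integer(n), k01 = k01, b01 = b01,
                 lambda02 = lambda02, lambda12 = lambda12,
                 censor_time = censor_time, p_ic = p_ic,
                 delta_mean = delta_mean, delta_var = delta_var,
                 eval_time = eval_time, m = as.integer(m),
                 nodes = as.integer(nodes)),
            class = "sim_config")
}

#' Draw one simulated dataset
#'
#' Latent times: \eqn{T_{01}} by inverse transform from
#' \eqn{P(T_{01} > t) = \exp(-k t^b)}, \eqn{T_{02} \sim Exp(\lambda_{02})},
#' and for subjects with the event of interest
#' \eqn{T_{12} \sim Exp(\lambda_{12})} added to \eqn{T_{01}}; administrative
#' censoring at the horizon. Observed records follow the examination scheme:
#' for interval-censored subjects `l1` is the last examination before the
#' event (or the last examination of follow-up), `t1` the first examination
#' at or after the event; events with no examination before death or
#' censoring are unobserved and recorded as `d1 = 0`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; a fixed seed gives a bit-identical dataset.
#' @return A [subject_records()] data frame with the exposure column `x` and
#'   latent-truth columns (`T01`, `T02`, `T12`, `delta01`, `delta02`,
#'   `delta12`, `scheme_ic`) retained for comparator analyses.
#' @export
draw_dataset <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n
  x <- as.integer(seq_len(n) <= n %/% 2)          # non-random: first half exposed
  k <- config$k01[x + 1L]; b <- config$b01[x + 1L]
  cmax <- config$censor_time

  T01 <- (-log(runif(n)) / k)^(1 / b)
  T02 <- rexp(n, config$lambda02)
  delta01 <- as.integer(T01 < T02 & T01 < cmax)
  delta02 <- as.integer(T02 <= T01 & T02 < cmax)
  T12 <- rep(NA_real_, n)
  death1 <- rep(NA_real_, n)
  delta12 <- integer(n)
  ev <- delta01 == 1
  T12[ev] <- rexp(sum(ev), config$lambda12)
  death1[ev] <- T01[ev] + T12[ev]
  delta12[ev] <- as.integer(death1[ev] < cmax)

  # end of follow-up (death from either state, or administrative censoring)
  tau <- ifelse(ev, pmin(death1, cmax),
                ifelse(delta02 == 1, T02, cmax))
  d2 <- as.integer(ifelse(ev, delta12, delta02))

  scheme_ic <- runif(n) < config$p_ic
  sdd <- sqrt(config$delta_var)

  l1 <- t1 <- numeric(n)
  d1 <- exact <- integer(n)
  for (i in seq_len(n)) {
    if (!scheme_ic[i]) {                          # exact observation scheme
      if (ev[i]) {
        d1[i] <- 1L; exact[i] <- 1L
        l1[i] <- t1[i] <- T01[i]
      } else {
        d1[i] <- 0L; exact[i] <- 1L
        l1[i] <- t1[i] <- tau[i]
      }
      next
    }
    # examination grid from e0 = 0 with positive N(Delta, sigma^2) increments
    e <- 0
    last_neg <- 0
    detected <- FALSE
    repeat {
      repeat {                                    # redraw until positive
        step <- rnorm(1, config$delta_mean, sdd)
        if (step > 0) break
      }
      e <- e + step
      if (e >= tau[i]) break
      if (ev[i] && e >= T01[i]) { detected <- TRUE; break }
      last_neg <- e
    }
    exact[i] <- 0L
    if (detected) {
      d1[i] <- 1L
      l1[i] <- last_neg; t1[i] <- e
    } else {
      d1[i] <- 0L                                 # includes unobserved events
      l1[i] <- last_neg; t1[i] <- tau[i]
    }
  }
  t2 <- ifelse(d1 == 1, ifelse(ev, pmin(death1, cmax), tau), tau)

  out <- data.frame(id = seq_len(n), x = x, l1 = l1, t1 = t1, d1 = d1,
                    exact = exact, t2 = t2, d2 = d2,
                    T01 = T01, T02 = T02, T12 = T12,
                    delta01 = delta01, delta02 = delta02, delta12 = delta12,
                    scheme_ic = as.integer(scheme_ic))
  out <- subject_records(out)
  attr(out, "censor_time") <- cmax
  out
}

#' Observed-data and exact-data views of a simulated dataset
#'
#' `observed_records()` strips the latent columns, leaving the observed
#' interval-censored records. `exact_records()` builds the "exact"
#' comparator data: the (in practice unobservable) right-censored
#' cause-specific records in which follow-up ends at the first event,
#' \eqn{T = \min(T_{01}, T_{02}, c)} with the cause indicator.
#'
#' @param dataset a data frame from [draw_dataset()].
#' @return A [subject_records()] data frame with the exposure column `x`.
#' @export
observed_records <- function(dataset) {
  subject_records(dataset[c("id", "x", "l1", "t1", "d1", "exact", "t2", "d2")])
}

#' @rdname observed_records
#' @export
exact_records <- function(dataset, censor_time = attr(dataset, "censor_time")) {
  if (is.null(censor_time)) censor_time <- max(dataset$t2)
  tt <- pmin(dataset$T01, dataset$T02, censor_time)
  d1 <- as.integer(dataset$delta01)
  d2 <- as.integer(dataset$delta02)
  subject_records(data.frame(
    id = dataset$id, x = dataset$x,
    l1 = tt, t1 = tt, d1 = d1, exact = 1L, t2 = tt, d2 = d2))
}

#' True values of the simulation estimands
#'
#' Deterministic quadrature of the cumulative incidence
#' \eqn{F_{01}(t) = \int_0^t h_{01}(u) \exp(-H_{01}(u) - H_{02}(u)) du} per
#' exposure arm under the generative parameters; the marginal cumulative
#' incidence is the equal-weight average of the two arms, the risk
#' difference their difference and the log relative risk the log of their
#' ratio.
#'
#' @param config a [sim_config()].
#' @param t evaluation time (defaults to `config$eval_time`).
#' @param nodes quadrature node count.
#' @return list with `cip0`, `cip1` (per arm), `cip` (marginal), `rd`,
#'   `lnrr`.
#' @export
true_values <- function(config, t = config$eval_time, nodes = 256L) {
  stopifnot(inherits(config, "sim_config"))
  lam <- config$lambda02
  arm <- function(a) {
    model <- illness_death_model(
      weibull_transition(config$k01[a], config$b01[a]),
      weibull_transition(lam, 1),
      weibull_transition(config$lambda12, 1))
    cumulative_incidence(t, model, nodes = nodes)
  }
  F0 <- arm(1L); F1 <- arm(2L)
  list(cip0 = F0, cip1 = F1, cip = (F0 + F1) / 2,
       rd = F1 - F0, lnrr = log(F1 / F0))
}

#' Wilson score interval for a coverage proportion
#'
#' @param k number of successes (intervals covering the truth).
#' @param n number of trials (valid replications).
#' @param conf confidence level.
#' @return vector `(estimate, lower, upper)` as proportions.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(estimate = p, lower = ctr - hw, upper = ctr + hw)
}

# Analyze one dataset with one method: returns one row per estimand with
# estimate, SE, CI and validity.  The marginal cumulative incidence is
# reported as the full-sample maximum-likelihood plug-in by default, with the
# pseudo-observation sandwich SE for inference; `cip_estimate =
# "pseudo_mean"` uses the intercept-only GEE solution (the mean
# pseudo-value, i.e. the jackknife bias-corrected estimate) instead.  The
# plug-in is the default because the jackknife correction is fragile under
# single highly influential observations (an exactly observed very early
# event can carry a pseudo-value of 10 or more), which the admissible-range
# filters do not catch.
.analyze_one <- function(records, config, loo_control = list(),
                         cip_estimate = c("plugin", "pseudo_mean")) {
  cip_estimate <- match.arg(cip_estimate)
  ps <- pseudo_obs(records, eval_times = config$eval_time, m = config$m,
                   nodes = config$nodes, control = loo_control)
  conv <- ps$valid
  z <- qnorm(0.975)

  g_cip <- pseudo_gee(ps, link = "identity")
  cip <- if (cip_estimate == "plugin") unname(ps$theta_full[1]) else
    unname(g_cip$beta[1])
  cip_se <- g_cip$se[1]
  if (is.finite(cip) && cip > 0) {
    sl <- cip_se / cip
    cip_ci <- c(exp(log(cip) - z * sl), exp(log(cip) + z * sl))
  } else cip_ci <- c(NA_real_, NA_real_)
  cip_valid <- conv && g_cip$converged && is.finite(cip) && cip > 0 && cip < 1

  zx <- records$x
  g_rd <- pseudo_gee(ps, covariates = data.frame(x = zx), link = "identity")
  rd <- unname(g_rd$beta[2]); rd_se <- g_rd$se[2]
  rd_ci <- c(rd - z * rd_se, rd + z * rd_se)
  rd_valid <- conv && g_rd$converged && is.finite(rd) && abs(rd) < 1

  g_rr <- tryCatch(
    pseudo_gee(ps, covariates = data.frame(x = zx), link = "log"),
    error = function(e) NULL)
  if (!is.null(g_rr)) {
    lnrr <- unname(g_rr$beta[2]); lnrr_se <- g_rr$se[2]
    lnrr_ci <- c(lnrr - z * lnrr_se, lnrr + z * lnrr_se)
    lnrr_valid <- conv && g_rr$converged && is.finite(lnrr) &&
      exp(lnrr) > 0.1 && exp(lnrr) < 10
  } else {
    lnrr <- lnrr_se <- NA_real_; lnrr_ci <- c(NA_real_, NA_real_)
    lnrr_valid <- FALSE
  }

  data.frame(
    estimand = c("cip", "rd", "lnrr"),
    estimate = c(cip, rd, lnrr),
    se = c(cip_se, rd_se, lnrr_se),
    lower = c(cip_ci[1], rd_ci[1], lnrr_ci[1]),
    upper = c(cip_ci[2], rd_ci[2], lnrr_ci[2]),
    valid = c(cip_valid, rd_valid, lnrr_valid))
}

#' Run the simulation study
#'
#' Replicates the full pipeline: draw a dataset, compute parametric
#' pseudo-observations under each method ("exact" uses the right-censored
#' cause-specific records that would be observed without interval censoring;
#' "ic" the interval-censored records), fit the GEE models for the marginal
#' cumulative incidence (intercept-only, identity link, log-scale CI), risk
#' difference (identity link) and log relative risk (log link), and
#' summarize operating characteristics over valid replications: median bias,
#' empirical SE (SD of estimates, n-1 denominator), relative empirical SE
#' against the exact method, average model SE, RMSE, and coverage of the 95%
#' intervals with a Wilson score CI. Replications failing the validity
#' filters (non-convergence of the full-sample or any leave-one-out fit, or
#' estimates outside their admissible ranges) are excluded per estimand and
#' counted.
#'
#' @param config a [sim_config()].
#' @param reps number of replications (>= 2).
#' @param seed master seed; per-replication seeds are derived
#'   deterministically.
#' @param methods subset of `c("exact", "ic")`.
#' @param cip_estimate point estimate used for the marginal cumulative
#'   incidence: the full-sample maximum-likelihood `"plugin"` (default) or
#'   the `"pseudo_mean"` (intercept-only GEE on the pseudo-values, i.e. the
#'   jackknife bias-corrected estimate); the SE is the pseudo-observation
#'   sandwich in both cases.
#' @param progress print a dot every 10 replications.
#' @return list with `metrics` (one row per method and estimand), `raw`
#'   (per-replication estimates) and `truth`.
#' @export
run_study <- function(config, reps, seed, methods = c("exact", "ic"),
                      cip_estimate = c("plugin", "pseudo_mean"),
                      progress = FALSE) {
  stopifnot(inherits(config, "sim_config"), reps >= 2)
  methods <- match.arg(methods, several.ok = TRUE)
  cip_estimate <- match.arg(cip_estimate)
  truth <- true_values(config)
  tv <- c(cip = truth$cip, rd = truth$rd, lnrr = truth$lnrr)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)

  raw <- vector("list", reps * length(methods))
  k <- 0L
  for (r in seq_len(reps)) {
    dat <- draw_dataset(config, rep_seeds[r])
    for (meth in methods) {
      recs <- if (meth == "exact") exact_records(dat) else observed_records(dat)
      row <- tryCatch(.analyze_one(recs, config, cip_estimate = cip_estimate),
                      error = function(e) data.frame(
                        estimand = c("cip", "rd", "lnrr"),
                        estimate = NA_real_, se = NA_real_,
                        lower = NA_real_, upper = NA_real_, valid = FALSE))
      row$method <- meth; row$rep <- r
      k <- k + 1L
      raw[[k]] <- row
    }
    if (progress && r %% 10L == 0L) { cat("."); if (r %% 500L == 0L) cat("\n") }
  }
  if (progress) cat("\n")
  raw <- do.call(rbind, raw)

  metrics <- list()
  emp_ref <- c(cip = NA_real_, rd = NA_real_, lnrr = NA_real_)
  for (meth in intersect(c("exact", "ic"), methods)) {
    for (est in c("cip", "rd", "lnrr")) {
      d <- raw[raw$method == meth & raw$estimand == est & raw$valid, ]
      if (nrow(d) == 0L) {
        metrics[[length(metrics) + 1L]] <- data.frame(
          method = meth, estimand = est, median_bias = NA_real_,
          empSE = NA_real_, rel_empSE = NA_real_, modSE = NA_real_,
          RMSE = NA_real_, coverage = NA_real_, coverage_lower = NA_real_,
          coverage_upper = NA_real_, valid = 0L)
        next
      }
      tval <- tv[[est]]
      empSE <- sd(d$estimate)
      if (meth == "exact") emp_ref[[est]] <- empSE
      cover <- d$lower <= tval & tval <= d$upper
      wc <- wilson_ci(sum(cover), nrow(d))
      metrics[[length(metrics) + 1L]] <- data.frame(
        method = meth, estimand = est,
        median_bias = median(d$estimate) - tval,
        empSE = empSE,
        rel_empSE = empSE / emp_ref[[est]],
        modSE = mean(d$se),
        RMSE = sqrt(mean((d$estimate - tval)^2)),
        coverage = 100 * wc[["estimate"]],
        coverage_lower = 100 * wc[["lower"]],
        coverage_upper = 100 * wc[["upper"]],
        valid = nrow(d))
    }
  }
  list(metrics = do.call(rbind, metrics), raw = raw, truth = truth)
}
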