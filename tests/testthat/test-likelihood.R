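test_that("records are classified into the six trajectories", {
  recs <- rbind(
    rec1(2, 2, 1, 1, 3, 0, id = 1),   # exact event, censored   -> 4
    rec1(2, 2, 1, 1, 3, 1, id = 2),   # exact event, death      -> 1
    rec1(3, 3, 0, 1, 3, 1, id = 3),   # no event, death         -> 2
    rec1(3, 3, 0, 1, 3, 0, id = 4),   # no event, censored      -> 5
    rec1(1, 2, 1, 0, 3, 1, id = 5),   # interval event, death   -> 3
    rec1(1, 2, 1, 0, 3, 0, id = 6))   # interval event, censored-> 6
  expect_equal(classify_trajectory(recs), c(4L, 1L, 2L, 5L, 3L, 6L))
})

test_that("inconsistent records are rejected with row numbers", {
  bad <- rbind(rec1(2, 2, 1, 1, 3, 0, id = 1),
               rec1(1.5, 1, 1, 1, 3, 0, id = 2))   # l1 > t1
  expect_error(subject_records(bad), "row 2")
  expect_error(subject_records(rec1(1, 2, 0, 1, 3, 0)), "t1 == t2")
  expect_error(subject_records(rec1(1, 2, 1, 1, 3, 0)), "l1 == t1")
  expect_error(subject_records(rec1(2, 2, 1, 0, 3, 0)), "l1 < t1")
  expect_error(subject_records(data.frame(id = 1, l1 = 1)), "missing required")
})

test_that("interval-censored contribution matches the exponential closed form", {
  m <- expo_model(0.1, 0.1, 0.4)
  # event in (1, 2], death at 3:
  # integral_1^2 0.1 e^{-0.2u} e^{-0.4(3-u)} 0.4 du = 0.2 e^{-1.2}(e^{0.4}-e^{0.2})
  L <- lik_contribution(rec1(1, 2, 1, 0, 3, 1), m)
  expect_equal(L, 0.2 * exp(-1.2) * (exp(0.4) - exp(0.2)), tolerance = 1e-10)
  # censored variant drops the h12 factor:
  # integral_1^2 0.1 e^{-0.2u} e^{-0.4(3-u)} du = 0.5 e^{-1.2}(e^{0.4}-e^{0.2})
  Lc <- lik_contribution(rec1(1, 2, 1, 0, 3, 0), m)
  expect_equal(Lc, 0.5 * exp(-1.2) * (exp(0.4) - exp(0.2)), tolerance = 1e-10)
  # exact event at 1, death at 3: e^{-0.2} 0.1 e^{-0.8} 0.4
  Le <- lik_contribution(rec1(1, 1, 1, 1, 3, 1), m)
  expect_equal(Le, 0.1 * 0.4 * exp(-0.2 - 0.8), tolerance = 1e-12)
})

test_that("no-observed-event contribution includes the unobserved-event integral", {
  m <- expo_model(0.1, 0.1, 0.4)
  # last negative exam at 1, death at 3: S(3) h02(3) + unobserved-event term
  L <- lik_contribution(rec1(1, 3, 0, 1, 3, 1), m)
  direct <- exp(-0.6) * 0.1
  unobs <- 0.2 * exp(-1.2) * (exp(0.6) - exp(0.2))
  expect_equal(L, direct + unobs, tolerance = 1e-10)
  # zero-length integral: right-censored subject contributes S(t2)
  L0 <- lik_contribution(rec1(3, 3, 0, 1, 3, 0), m)
  expect_equal(L0, exp(-0.6), tolerance = 1e-12)
})

test_that("interval contribution converges to its density limit as t1 -> l1", {
  m <- expo_model(0.1, 0.1, 0.4)
  w <- 1e-4
  L <- lik_contribution(rec1(1, 1 + w, 1, 0, 3, 1), m)
  dens <- exp(-0.2) * 0.1 * exp(-0.4 * 2) * 0.4
  expect_equal(L / w, dens, tolerance = 1e-3)
})

test_that("log-likelihood is additive and permutation invariant", {
  m <- expo_model()
  recs <- rbind(rec1(1, 2, 1, 0, 3, 1, id = 1),
                rec1(2, 2, 0, 1, 2, 0, id = 2),
                rec1(0.5, 0.5, 1, 1, 4, 1, id = 3))
  ll <- idm_loglik(recs, m)
  expect_equal(idm_loglik(recs[1, ], m), log(lik_contribution(recs[1, ], m)))
  dup <- rbind(recs, transform(recs, id = id + 10))
  expect_equal(idm_loglik(dup, m), 2 * ll, tolerance = 1e-12)
  expect_equal(idm_loglik(recs[c(3, 1, 2), ], m), ll, tolerance = 1e-12)
})

test_that("negative hazard at an exact event time zeroes the likelihood", {
  m <- illness_death_model(
    transition_model(spline_spec(boundary_knots = c(-2, 2)), c(0, -0.5)),
    weibull_transition(0.1, 1), weibull_transition(0.4, 1))
  expect_equal(lik_contribution(rec1(1, 1, 1, 1, 2, 0), m), 0)
  expect_equal(idm_loglik(rec1(1, 1, 1, 1, 2, 0), m), -Inf)
})

test_that("analytic gradient agrees with finite differences of the likelihood", {
  cfg <- sim_config(n = 60)
  recs <- observed_records(draw_dataset(cfg, 31))
  specs <- default_specs(recs, m = 1)
  cache <- icpseudo:::.build_cache(recs, specs, 64)
  set.seed(8)
  g <- c(-2.5, 0.6, 0.05, -2.2, 0.9, -0.03, -1.1, 1.1, 0.02)
  r <- icpseudo:::cpp_idm_loglik_grad(cache, g, 0L)
  fd <- vapply(seq_along(g), function(j) {
    h <- 1e-6 * (1 + abs(g[j]))
    up <- g; up[j] <- up[j] + h
    dn <- g; dn[j] <- dn[j] - h
    (icpseudo:::cpp_idm_loglik(cache, up, 0L) -
       icpseudo:::cpp_idm_loglik(cache, dn, 0L)) / (2 * h)
  }, numeric(1))
  expect_equal(r$gradient, fd, tolerance = 1e-5)
})

test_that("m = 0 fit on exact data matches independent Weibull MLEs", {
  cfg <- sim_config(n = 400)
  dat <- draw_dataset(cfg, 99)
  ex <- exact_records(dat)
  fit <- fit_idm(ex, specs = m0_specs())
  expect_true(fit$convergence$converged)
  expect_false(fit$active12)
  # flexsurv weibullPH: H(t) = scale * t^shape, the same parameterization
  f1 <- flexsurv::flexsurvreg(survival::Surv(t1, d1) ~ 1, data = ex,
                              dist = "weibullPH")
  f2 <- flexsurv::flexsurvreg(survival::Surv(t2, d2) ~ 1, data = ex,
                              dist = "weibullPH")
  expect_equal(fit$model$t01$gamma,
               unname(c(log(f1$res["scale", "est"]), f1$res["shape", "est"])),
               tolerance = 1e-4)
  expect_equal(fit$model$t02$gamma,
               unname(c(log(f2$res["scale", "est"]), f2$res["shape", "est"])),
               tolerance = 1e-4)
})

test_that("the fit is a local maximum of the log-likelihood", {
  cfg <- sim_config(n = 150, k01 = c(0.25, 0.4), b01 = c(0.8, 0.7))
  recs <- observed_records(draw_dataset(cfg, 12))
  fit <- fit_idm(recs, m = 1)
  expect_true(fit$convergence$converged)
  ll0 <- idm_loglik(recs, fit$model)
  expect_equal(ll0, fit$loglik, tolerance = 1e-8)
  g <- icpseudo:::.stack_gamma(fit$model)
  specs <- fit$specs
  for (j in seq_along(g)) {
    for (d in c(-0.05, 0.05)) {
      gp <- g; gp[j] <- gp[j] + d
      expect_lt(idm_loglik(recs, icpseudo:::.unstack_gamma(gp, specs)), ll0)
    }
  }
})

test_that("initial values are deterministic and a no-op without candidates", {
  cfg <- sim_config(n = 120)
  recs <- observed_records(draw_dataset(cfg, 3))
  specs <- default_specs(recs, m = 1)
  i1 <- initial_values(recs, specs, seed = 77)
  i2 <- initial_values(recs, specs, seed = 77)
  expect_identical(i1, i2)
  i3 <- initial_values(recs, specs, seed = 78)
  expect_false(identical(i1, i3))

  # all-exact data: no interval-censored records, no unobserved-event windows
  ex <- exact_records(draw_dataset(cfg, 3))
  specs_e <- m0_specs()
  a <- initial_values(ex, specs_e, seed = 1)
  b <- initial_values(ex, specs_e, seed = 999)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the midpoint initializer speeds up convergence over naive values", {
  cfg <- sim_config(n = 500)
  recs <- observed_records(draw_dataset(cfg, 41))
  specs <- default_specs(recs, m = 1)
  naive <- list(gamma01 = c(0, 1, 0), gamma02 = c(0, 1, 0),
                gamma12 = c(0, 1, 0))
  f_smart <- fit_idm(recs, specs = specs, init_seed = 1)
  f_naive <- fit_idm(recs, specs = specs, init = naive)
  expect_true(f_smart$convergence$converged)
  expect_equal(f_smart$loglik, f_naive$loglik, tolerance = 1e-5)
  expect_lt(f_smart$convergence$iterations, f_naive$convergence$iterations)
})
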