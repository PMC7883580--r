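test_that("intercept-only solutions are the (log) mean of the pseudo-values", {
  set.seed(7)
  th <- rnorm(60, 0.15, 0.3)
  fit <- pseudo_gee(th, link = "identity")
  expect_equal(unname(fit$beta), mean(th), tolerance = 1e-12)
  fit_log <- pseudo_gee(th, link = "log")
  expect_equal(unname(fit_log$beta), log(mean(th)), tolerance = 1e-9)
  expect_true(fit_log$converged)
  expect_lt(fit_log$residual_norm, 1e-8)
})

test_that("identity link with a binary covariate gives group mean differences", {
  set.seed(8)
  z <- rep(0:1, each = 30)
  th <- rnorm(60, 0.1 + 0.07 * z, 0.25)
  fit <- pseudo_gee(th, covariates = data.frame(x = z), link = "identity")
  expect_equal(unname(fit$beta["x"]),
               mean(th[z == 1]) - mean(th[z == 0]), tolerance = 1e-12)
  # log link: coefficient is the log ratio of group means
  th_pos <- abs(th) + 0.05
  fit_log <- pseudo_gee(th_pos, covariates = data.frame(x = z), link = "log")
  expect_equal(unname(fit_log$beta["x"]),
               log(mean(th_pos[z == 1]) / mean(th_pos[z == 0])),
               tolerance = 1e-8)
})

test_that("identity-link GEE with independence equals ordinary least squares", {
  set.seed(9)
  z1 <- rnorm(50); z2 <- rbinom(50, 1, 0.4)
  th <- 0.1 + 0.05 * z1 - 0.02 * z2 + rnorm(50, 0, 0.2)
  fit <- pseudo_gee(th, covariates = data.frame(z1 = z1, z2 = z2))
  ref <- lm(th ~ z1 + z2)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-10)
})

test_that("sandwich SE of the mean matches the robust formula", {
  set.seed(10)
  th <- rnorm(40, 0.2, 0.3)
  fit <- pseudo_gee(th, link = "identity")
  n <- length(th)
  expect_equal(unname(fit$se), sqrt(sum((th - mean(th))^2)) / n,
               tolerance = 1e-12)
  # HC1-type correction inflates by sqrt(n / (n - p))
  fit1 <- pseudo_gee(th, link = "identity", hc1 = TRUE)
  expect_equal(unname(fit1$se), unname(fit$se) * sqrt(n / (n - 1)),
               tolerance = 1e-12)
})

test_that("multiple evaluation times get time-specific intercepts and clustered meat", {
  set.seed(11)
  Y <- cbind(rnorm(35, 0.1, 0.2), rnorm(35, 0.2, 0.25))
  fit <- pseudo_gee(Y, link = "identity")
  expect_equal(unname(fit$beta), colMeans(Y), tolerance = 1e-12)
  expect_equal(dim(fit$vcov), c(2L, 2L))
  # meat clusters on subjects: off-diagonal covariance reflects within-subject
  # correlation of the residuals
  r <- sweep(Y, 2, colMeans(Y))
  expect_equal(fit$vcov[1, 2], sum(r[, 1] * r[, 2]) / 35^2, tolerance = 1e-12)
})

test_that("effect estimates use the documented CI scales", {
  set.seed(12)
  z <- rep(0:1, each = 40)
  th <- rnorm(80, 0.12 + 0.06 * z, 0.3)
  fit <- pseudo_gee(th, covariates = data.frame(x = z), link = "identity")
  est <- effect_estimates(fit)
  risk <- est[est$quantity == "risk", ]
  # log-scale CI: exp(ln r +/- 1.96 se/r)
  expect_equal(risk$lower,
               exp(log(risk$estimate) - qnorm(0.975) * risk$se / risk$estimate))
  rd <- est[est$quantity == "risk_difference", ]
  expect_equal(rd$upper - rd$estimate, rd$estimate - rd$lower)  # symmetric
  # scale equivariance of the log-scale CI
  expect_equal(risk$upper / risk$estimate,
               exp(qnorm(0.975) * risk$se / risk$estimate))

  fit_log <- pseudo_gee(abs(th) + 0.02, covariates = data.frame(x = z),
                        link = "log")
  est_log <- effect_estimates(fit_log)
  rr <- est_log[est_log$quantity == "relative_risk", ]
  lr <- est_log[est_log$quantity == "log_relative_risk", ]
  expect_equal(rr$estimate, exp(lr$estimate))
  expect_equal(rr$lower, exp(lr$lower))
})

test_that("validity filters apply the admissible ranges", {
  tab <- function(q, e) data.frame(quantity = q, term = "x", estimate = e,
                                   se = 0.1, lower = e - 0.1, upper = e + 0.1)
  expect_false(validate_estimates(tab("risk", 1.2)))
  expect_false(validate_estimates(tab("risk", -0.01)))
  expect_false(validate_estimates(tab("relative_risk", 12)))
  expect_false(validate_estimates(tab("relative_risk", 0.05)))
  expect_false(validate_estimates(tab("risk_difference", 1.3)))
  good <- rbind(tab("risk", 0.12), tab("risk_difference", 0.07),
                tab("relative_risk", 1.7))
  expect_true(validate_estimates(good))
  expect_false(validate_estimates(good, converged = FALSE))
})

test_that("degenerate GEE inputs are rejected", {
  expect_error(pseudo_gee(rnorm(10), covariates = data.frame(x = rep(1, 10))),
               "rank deficient")
  expect_error(pseudo_gee(rnorm(20) - 10, link = "log"), "positive mean")
})
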