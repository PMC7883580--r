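#' Generalized estimating equations on pseudo-observations
#'
#' Regresses pseudo-observations \eqn{\theta_i} on covariates through a link
#' \eqn{g}: \eqn{g(E[I(T_1 \le t, D_1 = 1)]) = \beta^\top Z_i}, with
#' \eqn{g(x) = x} for risk differences and \eqn{g(x) = \ln x} for relative
#' risks. Coefficients solve the estimating equation
#' \deqn{\sum_i \left(\partial_\beta g^{-1}(\beta^\top Z_i)\right)^\top
#'   V_i^{-1} (\theta_i - g^{-1}(\beta^\top Z_i)) = 0,}
#' with an independence working covariance (for a single evaluation time the
#' scalar working variance cancels). The variance is the sandwich
#' \eqn{A^{-1} B A^{-\top}} with bread \eqn{A = \sum_i D_i^\top V_i^{-1} D_i}
#' and meat \eqn{B = \sum_i (D_i^\top V_i^{-1} r_i)(D_i^\top V_i^{-1}
#' r_i)^\top}, clustered on subjects across evaluation times. By default the
#' meat carries no small-sample correction; `hc1 = TRUE` multiplies it by
#' \eqn{n / (n - p)}.
#'
#' With several evaluation times the design gains one intercept per time
#' (time-specific baseline risks) while covariate effects are shared.
#'
#' @param pseudo a [pseudo_obs()] object, or a numeric vector/matrix of
#'   pseudo-values (subjects in rows, evaluation times in columns).
#' @param covariates optional data frame or matrix of subject-level
#'   covariates (no intercept column; it is added automatically).
#' @param link `"identity"` or `"log"`.
#' @param hc1 apply the HC1-type small-sample factor to the meat.
#' @param tol convergence tolerance on the sup-norm of the estimating
#'   function.
#' @param max_iter maximum Fisher-scoring iterations (log link).
#' @return Object of class `"pseudo_gee"`: `beta`, `vcov` (sandwich), `se`,
#'   `ci` (95%), `link`, `converged`, `residual_norm`, `n`, plus the inputs
#'   needed by [effect_estimates()].
#' @export
pseudo_gee <- function(pseudo, covariates = NULL,
                       link = c("identity", "log"), hc1 = FALSE,
                       tol = 1e-10, max_iter = 100L) {
  link <- match.arg(link)
  Y <- if (inherits(pseudo, "pseudo_obs")) pseudo$pseudo else as.matrix(pseudo)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  n <- nrow(Y); Tn <- ncol(Y)

  Zc <- if (is.null(covariates)) matrix(numeric(0), n, 0) else {
    z <- as.matrix(as.data.frame(covariates))
    storage.mode(z) <- "double"
    z
  }
  if (nrow(Zc) != n && ncol(Zc) > 0)
    stop("covariates must have one row per subject", call. = FALSE)

  # stacked design: time-specific intercepts, shared covariate effects
  X <- cbind(kronecker(diag(Tn), rep(1, n)),
             do.call(rbind, replicate(Tn, Zc, simplify = FALSE)))
  colnames(X) <- c(if (Tn == 1) "(Intercept)" else paste0("(Intercept:t", seq_len(Tn), ")"),
                   colnames(Zc))
  y <- as.vector(Y)
  subj <- rep(seq_len(n), times = Tn)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)

  if (link == "identity") {
    fit0 <- stats::lm.fit(X, y)
    beta <- fit0$coefficients
    mu <- drop(X %*% beta)
    Dm <- X
    converged <- TRUE
  } else {
    mbar <- mean(y)
    if (mbar <= 0)
      stop("log link requires a positive mean pseudo-value", call. = FALSE)
    beta <- c(log(mbar), rep(0, p - 1))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      mu <- exp(drop(X %*% beta))
      U <- colSums(X * (mu * (y - mu)))
      if (max(abs(U)) < tol) { converged <- TRUE; break }
      Ainf <- crossprod(X * mu)                 # Fisher information of the EE
      step <- solve(Ainf, U)
      # damped step: halve until the estimating function norm decreases
      lam <- 1
      repeat {
        bnew <- beta + lam * step
        munew <- exp(drop(X %*% bnew))
        Unew <- colSums(X * (munew * (y - munew)))
        if (all(is.finite(Unew)) &&
            (max(abs(Unew)) < max(abs(U)) || lam < 1e-8)) break
        lam <- lam / 2
      }
      beta <- bnew
    }
    mu <- exp(drop(X %*% beta))
    converged <- converged || max(abs(colSums(X * (mu * (y - mu))))) < tol
    Dm <- X * mu
  }
  names(beta) <- colnames(X)
  resid <- y - mu
  U <- colSums(Dm * resid)

  A <- crossprod(Dm)
  scores <- rowsum(Dm * resid, subj)            # per-subject estimating scores
  B <- crossprod(scores)
  if (hc1) B <- B * n / (n - p)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% t(Ainv)
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(pmax(diag(V), 0))
  z <- qnorm(0.975)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)

  structure(
    list(beta = beta, vcov = V, se = se, ci = ci, link = link,
         converged = converged, residual_norm = max(abs(U)),
         n = n, n_times = Tn, covariate_names = colnames(Zc),
         X = X, y = y),
    class = "pseudo_gee")
}

#' @export
print.pseudo_gee <- function(x, ...) {
  cat(sprintf("Pseudo-observation GEE (%s link, n = %d%s)\n", x$link, x$n,
              if (x$converged) "" else ", NOT converged"))
  tab <- data.frame(estimate = x$beta, se = x$se,
                    lower = x$ci[, 1], upper = x$ci[, 2])
  print(round(tab, 4))
  invisible(x)
}

#' Risk, risk-difference and relative-risk estimates with 95% CIs
#'
#' Transforms a fitted [pseudo_gee()] into estimates on interpretable
#' scales. Confidence intervals for the cumulative incidence (risk) are
#' computed on the logarithmic scale,
#' \eqn{\exp(\ln\hat\theta \pm 1.96\, SE(\ln\hat\theta))} with
#' \eqn{SE(\ln\hat\theta) = SE(\hat\theta)/\hat\theta} by the delta method,
#' to respect the asymmetry of the risk scale. Risk-difference intervals are
#' symmetric on the natural scale; relative-risk intervals are symmetric on
#' the log scale and then exponentiated.
#'
#' For an identity-link fit the rows are the baseline risk (intercept) and
#' one risk difference per covariate; for a log-link fit, the baseline risk
#' and one relative risk (with its log) per covariate.
#'
#' @param fit a [pseudo_gee()] object.
#' @return data frame with columns `quantity`, `term`, `estimate`, `se`,
#'   `lower`, `upper`.
#' @export
effect_estimates <- function(fit) {
  stopifnot(inherits(fit, "pseudo_gee"))
  z <- qnorm(0.975)
  rows <- list()
  nint <- fit$n_times
  for (k in seq_len(nint)) {
    b0 <- fit$beta[k]; s0 <- fit$se[k]
    risk <- if (fit$link == "identity") b0 else exp(b0)
    if (risk > 0) {
      se_log <- if (fit$link == "identity") s0 / risk else s0
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = "risk", term = names(fit$beta)[k], estimate = risk,
        se = if (fit$link == "identity") s0 else risk * s0,
        lower = exp(log(risk) - z * se_log),
        upper = exp(log(risk) + z * se_log))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = "risk", term = names(fit$beta)[k], estimate = risk,
        se = NA_real_, lower = NA_real_, upper = NA_real_)
    }
  }
  if (length(fit$beta) > nint) {
    for (k in (nint + 1L):length(fit$beta)) {
      b <- fit$beta[k]; s <- fit$se[k]
      if (fit$link == "identity") {
        rows[[length(rows) + 1L]] <- data.frame(
          quantity = "risk_difference", term = names(fit$beta)[k],
          estimate = b, se = s, lower = b - z * s, upper = b + z * s)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          quantity = "log_relative_risk", term = names(fit$beta)[k],
          estimate = b, se = s, lower = b - z * s, upper = b + z * s)
        rows[[length(rows) + 1L]] <- data.frame(
          quantity = "relative_risk", term = names(fit$beta)[k],
          estimate = exp(b), se = exp(b) * s,
          lower = exp(b - z * s), upper = exp(b + z * s))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validity filter for pseudo-observation regression results
#'
#' A result is valid when every underlying fit converged and every
#' applicable estimate lies in its admissible range: cumulative incidence in
#' \eqn{(0, 1)}, risk difference in \eqn{(-1, 1)}, relative risk in
#' \eqn{(10^{-1}, 10)}.
#'
#' @param estimates data frame from [effect_estimates()] (or a
#'   [pseudo_gee()] fit, in which case estimates are derived first).
#' @param converged logical: did all underlying fits (full sample and every
#'   leave-one-out refit) converge?
#' @return single logical.
#' @export
validate_estimates <- function(estimates, converged = TRUE) {
  if (inherits(estimates, "pseudo_gee")) {
    converged <- converged && estimates$converged
    estimates <- effect_estimates(estimates)
  }
  if (!isTRUE(converged)) return(FALSE)
  ok <- TRUE
  for (i in seq_len(nrow(estimates))) {
    e <- estimates$estimate[i]
    ok <- ok && switch(
      estimates$quantity[i],
      risk = is.finite(e) && e > 0 && e < 1,
      risk_difference = is.finite(e) && e > -1 && e < 1,
      relative_risk = is.finite(e) && e > 0.1 && e < 10,
      log_relative_risk = is.finite(e) && e > -log(10) && e < log(10),
      TRUE)
  }
  ok
}
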