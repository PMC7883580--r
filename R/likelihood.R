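#' @keywords internal
.build_cache <- function(records, specs, nodes) {
  cpp_build_cache(records$l1, records$t1, records$t2,
                  as.integer(records$d1), as.integer(records$exact),
                  as.integer(records$d2),
                  list(specs$t01$internal_knots, specs$t02$internal_knots,
                       specs$t12$internal_knots),
                  list(specs$t01$boundary_knots, specs$t02$boundary_knots,
                       specs$t12$boundary_knots),
                  as.integer(nodes))
}

.model_specs <- function(model) {
  list(t01 = model$t01$spec, t02 = model$t02$spec, t12 = model$t12$spec)
}

.stack_gamma <- function(model) {
  c(model$t01$gamma, model$t02$gamma, model$t12$gamma)
}

.unstack_gamma <- function(par, specs) {
  p <- vapply(specs, function(s) s$dim, integer(1))
  illness_death_model(
    transition_model(specs$t01, par[seq_len(p[1])]),
    transition_model(specs$t02, par[p[1] + seq_len(p[2])]),
    transition_model(specs$t12, par[p[1] + p[2] + seq_len(p[3])]))
}

#' Likelihood contributions of subject records under an illness-death model
#'
#' Returns the per-subject likelihood contribution \eqn{L_i}. Writing
#' \eqn{E(u, t_2) = \exp(-(H_{12}(t_2) - H_{12}(u)))} for survival in state 1:
#' an exactly observed event at \eqn{t_1} contributes
#' \eqn{S(t_1) h_{01}(t_1) E(t_1, t_2) h_{12}(t_2)^{d_2}}; a subject with no
#' observed event contributes
#' \eqn{S(t_2) h_{02}(t_2)^{d_2} + \int_{l_1}^{t_2} S(u) h_{01}(u)
#' E(u, t_2) h_{12}(t_2)^{d_2} du} (the integral covers a possible unobserved
#' event after the last negative examination); and an interval-censored event
#' contributes the same integral over \eqn{(l_1, t_1)}. The convention
#' \eqn{0^0 = 1} applies to the \eqn{d_2} exponent. A contribution that is
#' not positive (a negative fitted hazard where a density is required) is
#' returned as 0 and makes the log-likelihood \eqn{-\infty}.
#'
#' @param records a [subject_records()] data frame.
#' @param model an [illness_death_model()].
#' @param nodes Gauss-Legendre node count for the interval integrals.
#' @return `lik_contribution()`: numeric vector of contributions;
#'   `idm_loglik()`: the total log-likelihood (may be `-Inf`).
#' @export
lik_contribution <- function(records, model, nodes = 64L) {
  records <- subject_records(records)
  cache <- .build_cache(records, .model_specs(model), nodes)
  cpp_contributions(cache, .stack_gamma(model))
}

#' @rdname lik_contribution
#' @export
idm_loglik <- function(records, model, nodes = 64L) {
  records <- subject_records(records)
  cache <- .build_cache(records, .model_specs(model), nodes)
  cpp_idm_loglik(cache, .stack_gamma(model), 0L)
}

# ---------------------------------------------------------------------------
# Optimization on a prebuilt cache (shared by full-sample and jackknife fits)
# ---------------------------------------------------------------------------
.fit_control <- function(control = list()) {
  ctrl <- list(maxit = 500L, reltol = 1e-10, restarts = 1L, grad_tol = 1e-5)
  ctrl[names(control)] <- control
  ctrl
}

.fit_on_cache <- function(cache, p, init, skip = 0L, active3 = TRUE,
                          control = list()) {
  ctrl <- .fit_control(control)
  ptot <- sum(p)
  act <- if (active3) seq_len(ptot) else seq_len(p[1] + p[2])
  fixed <- init
  expand <- function(par) { fixed[act] <- par; fixed }

  # fn is called repeatedly during the line search, gr once per iteration:
  # keep fn gradient-free.
  fn <- function(par) {
    v <- cpp_idm_loglik(cache, expand(par), as.integer(skip))
    if (!is.finite(v)) 1e10 else -v
  }
  gr <- function(par) {
    r <- cpp_idm_loglik_grad(cache, expand(par), as.integer(skip))
    if (!is.finite(r$loglik)) numeric(length(par)) else -r$gradient[act]
  }

  par0 <- init[act]
  if (!is.finite(cpp_idm_loglik(cache, init, as.integer(skip))))
    stop("initial coefficients give a zero likelihood contribution", call. = FALSE)
  opt <- optim(par0, fn, gr, method = "BFGS",
               control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  tries <- 0L
  while (opt$convergence != 0L && tries < ctrl$restarts) {
    tries <- tries + 1L
    opt <- optim(opt$par, fn, gr, method = "BFGS",
                 control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  }
  # Newton polish: BFGS stops on relative log-likelihood change, which can
  # leave the gradient larger than the sup-norm criterion; a few chord-Newton
  # steps with the local Hessian tighten it.
  par_full <- expand(opt$par)
  pol <- NULL
  cholH <- tryCatch(chol(.nll_hessian(cache, par_full, skip, act)),
                    error = function(e) NULL)
  if (!is.null(cholH))
    pol <- .newton_polish(cache, par_full, skip, act, cholH)
  # convergence requires the gradient criterion, not just the relative-change
  # stop: a likelihood whose supremum lies at a boundary (e.g. a 1->2
  # transition with almost no events in a subsample) can satisfy reltol while
  # the gradient stays large, and such fits are flagged, not accepted.
  if (!is.null(pol)) {
    list(par = pol$par, loglik = pol$loglik,
         converged = is.finite(pol$loglik) &&
           pol$gradient_norm < ctrl$grad_tol,
         iterations = unname(opt$counts["function"]),
         gradient_norm = pol$gradient_norm)
  } else {
    g <- cpp_idm_loglik_grad(cache, par_full, as.integer(skip))
    gn <- if (is.finite(g$loglik)) max(abs(g$gradient[act])) else Inf
    list(par = par_full,
         loglik = -opt$value,
         converged = is.finite(opt$value) && gn < ctrl$grad_tol,
         iterations = unname(opt$counts["function"]),
         gradient_norm = gn)
  }
}

# chord-Newton iteration with backtracking from a point near the optimum;
# the short backtracking budget makes it stall fast (rather than crawl) on
# surfaces whose supremum lies at a boundary.
.newton_polish <- function(cache, par, skip, act, cholH,
                           gtol = 1e-8, maxit = 50L) {
  r <- cpp_idm_loglik_grad(cache, par, as.integer(skip))
  if (!is.finite(r$loglik)) return(NULL)
  ok <- FALSE
  for (it in seq_len(maxit)) {
    g <- r$gradient[act]
    if (max(abs(g)) < gtol) { ok <- TRUE; break }
    step <- backsolve(cholH, backsolve(cholH, g, transpose = TRUE))
    lam <- 1
    repeat {
      cand <- par; cand[act] <- cand[act] + lam * step
      rc <- cpp_idm_loglik_grad(cache, cand, as.integer(skip))
      if (is.finite(rc$loglik) && rc$loglik >= r$loglik - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-3) break
    }
    if (lam < 1e-3) break
    par <- cand; r <- rc
  }
  gn <- max(abs(r$gradient[act]))
  list(par = par, loglik = r$loglik, ok = ok || gn < gtol,
       gradient_norm = gn)
}

# Hessian of the negative log-likelihood by central differences of the
# analytic gradient (restricted to the active coordinates).
.nll_hessian <- function(cache, par, skip = 0L, act = seq_along(par)) {
  pa <- length(act)
  H <- matrix(0, pa, pa)
  for (j in seq_len(pa)) {
    h <- 1e-5 * (1 + abs(par[act[j]]))
    up <- par; up[act[j]] <- up[act[j]] + h
    dn <- par; dn[act[j]] <- dn[act[j]] - h
    gu <- cpp_idm_loglik_grad(cache, up, as.integer(skip))$gradient[act]
    gd <- cpp_idm_loglik_grad(cache, dn, as.integer(skip))$gradient[act]
    H[j, ] <- -(gu - gd) / (2 * h)
  }
  (H + t(H)) / 2
}

# Leave-one-out refit by chord Newton: reuse the (factored) full-sample
# Hessian and iterate analytic-gradient steps from the warm start.  Falls
# back to the BFGS path when the iteration stalls.
.loo_refit <- function(cache, p, warm, cholH, skip, act, active3,
                       control = list()) {
  pol <- .newton_polish(cache, warm, skip, act, cholH)
  if (!is.null(pol) && pol$ok)
    return(list(par = pol$par, loglik = pol$loglik, converged = TRUE))
  ctrl <- control
  if (is.null(ctrl$restarts)) ctrl$restarts <- 0L
  if (is.null(ctrl$maxit)) ctrl$maxit <- 200L
  .fit_on_cache(cache, p, warm, skip = skip, active3 = active3,
                control = ctrl)
}

# Per-transition exponential rates, the documented fallback initial values.
.exp_init <- function(records, specs) {
  ev_time <- ifelse(records$d1 == 1,
                    ifelse(records$exact == 1, records$t1,
                           (records$l1 + records$t1) / 2),
                    records$t2)
  rate <- function(ev, pt) max(ev, 0.5) / max(pt, 1e-8)
  r01 <- rate(sum(records$d1), sum(ev_time))
  r02 <- rate(sum(records$d2[records$d1 == 0]), sum(ev_time))
  has <- records$d1 == 1
  r12 <- rate(sum(records$d2[has]), sum(pmax(records$t2[has] - ev_time[has], 0)))
  list(gamma01 = c(log(r01), 1, rep(0, specs$t01$dim - 2L)),
       gamma02 = c(log(r02), 1, rep(0, specs$t02$dim - 2L)),
       gamma12 = c(log(r12), 1, rep(0, specs$t12$dim - 2L)))
}

# Single-transition flexible parametric fit on right-censored data with
# optional delayed entry; used only to construct initial values.
.fit_transition <- function(time, status, spec, entry = NULL, init = NULL,
                            control = list()) {
  ctrl <- .fit_control(control)
  keep <- if (is.null(entry)) rep(TRUE, length(time)) else time > entry
  time <- time[keep]; status <- status[keep]
  entry <- if (is.null(entry)) NULL else entry[keep]
  if (!length(time) || sum(status) < 1)
    stop("no usable events for transition sub-fit", call. = FALSE)
  B <- ncs_basis(log(time), spec)
  D <- ncs_basis_deriv(log(time), spec)
  hasE <- !is.null(entry)
  if (hasE) {
    pos <- entry > 0
    Be <- ncs_basis(log(pmax(entry, 1e-300)), spec)
    Be[!pos, ] <- 0           # H(0) = 0: zero rows drop the entry term
  }
  logt <- log(time)
  ev <- status == 1
  nllgr <- function(g) {
    s <- drop(B %*% g); sp <- drop(D %*% g)
    if (any(sp[ev] <= 0)) return(list(nll = 1e10, gr = numeric(length(g))))
    H <- exp(pmin(s, 690))
    ll <- sum(log(sp[ev])) - sum(logt[ev]) + sum(s[ev]) - sum(H)
    gr <- colSums(D[ev, , drop = FALSE] / sp[ev]) +
      colSums(B[ev, , drop = FALSE]) - colSums(H * B)
    if (hasE) {
      se <- drop(Be %*% g)
      He <- ifelse(pos, exp(pmin(se, 690)), 0)
      ll <- ll + sum(He)
      gr <- gr + colSums(He * Be)
    }
    if (!is.finite(ll)) return(list(nll = 1e10, gr = numeric(length(g))))
    list(nll = -ll, gr = -gr)
  }
  if (is.null(init)) {
    pt <- if (hasE) sum(time - entry) else sum(time)
    init <- c(log(max(sum(status), 0.5) / max(pt, 1e-8)), 1, rep(0, spec$dim - 2L))
  }
  opt <- optim(init, function(g) nllgr(g)$nll, function(g) nllgr(g)$gr,
               method = "BFGS", control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  list(gamma = opt$par, loglik = -opt$value, converged = opt$convergence == 0L)
}

#' Initial values for the illness-death likelihood
#'
#' Builds starting coefficients by (i) fitting the 0->1 transition as a
#' flexible parametric survival model with interval-censored events imputed
#' at their interval midpoints; (ii) computing, for every subject without an
#' observed event, the probability of an unobserved event between the last
#' negative examination `l1` and the end of follow-up `t2` from the predicted
#' event-free curve of that fit; (iii) randomly assigning unobserved events
#' (at the midpoint of `(l1, t2)`) by individual Bernoulli draws; and (iv)
#' fitting the 0->2 and 1->2 transitions on the augmented data, the latter
#' with delayed entry at the (imputed) event time. Any sub-fit failure falls
#' back to per-transition exponential rates.
#'
#' @param records a [subject_records()] data frame.
#' @param specs named list of three [spline_spec()] objects
#'   (`t01`, `t02`, `t12`).
#' @param seed integer seed for the Bernoulli assignment (fixed seed gives a
#'   bit-identical initial vector).
#' @param prob `"conditional"` computes the unobserved-event probability as
#'   \eqn{(\hat S(l_1) - \hat S(t_2)) / \hat S(l_1)} (the probability given
#'   event-free status at `l1`); `"marginal"` uses the unconditional survival
#'   difference.
#' @return list with components `gamma01`, `gamma02`, `gamma12`.
#' @export
initial_values <- function(records, specs, seed,
                           prob = c("conditional", "marginal")) {
  records <- subject_records(records)
  prob <- match.arg(prob)
  fallback <- .exp_init(records, specs)

  ev_time <- ifelse(records$exact == 1, records$t1,
                    (records$l1 + records$t1) / 2)
  fit01 <- tryCatch(
    .fit_transition(ifelse(records$d1 == 1, ev_time, records$t2),
                    records$d1, specs$t01),
    error = function(e) NULL)
  if (is.null(fit01) || !fit01$converged)
    return(fallback)
  g01 <- fit01$gamma

  S01 <- function(t) {
    out <- rep(1, length(t))
    pos <- t > 0
    out[pos] <- exp(-exp(pmin(drop(ncs_basis(log(t[pos]), specs$t01) %*% g01), 690)))
    out
  }
  cand <- which(records$d1 == 0 & records$l1 < records$t2)
  has_event <- records$d1 == 1
  imput <- ev_time
  if (length(cand)) {
    Sl <- S01(records$l1[cand]); St <- S01(records$t2[cand])
    p_unobs <- if (prob == "conditional") (Sl - St) / pmax(Sl, 1e-12) else Sl - St
    p_unobs <- pmin(pmax(p_unobs, 0), 1)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    assign_unobs <- runif(length(cand)) < p_unobs
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
    idx <- cand[assign_unobs]
    has_event[idx] <- TRUE
    imput[idx] <- (records$l1[idx] + records$t2[idx]) / 2
  }

  fit02 <- tryCatch(
    .fit_transition(ifelse(has_event, imput, records$t2),
                    ifelse(has_event, 0L, records$d2), specs$t02),
    error = function(e) NULL)
  fit12 <- tryCatch(
    if (any(has_event))
      .fit_transition(records$t2[has_event], records$d2[has_event], specs$t12,
                      entry = imput[has_event])
    else NULL,
    error = function(e) NULL)

  list(gamma01 = g01,
       gamma02 = if (!is.null(fit02) && fit02$converged) fit02$gamma else fallback$gamma02,
       gamma12 = if (!is.null(fit12) && fit12$converged) fit12$gamma else fallback$gamma12)
}

#' Default knot placement for a dataset
#'
#' Places `m` internal knots per transition from transition-specific
#' event-time proxies: exact event times and interval midpoints for 0->1,
#' death times without a prior observed event for 0->2, and death times after
#' an observed event for 1->2. When a transition has too few distinct
#' proxies the pool widens to all death times, then all follow-up times, and
#' finally the number of internal knots for that transition is reduced.
#'
#' @param records a [subject_records()] data frame.
#' @param m requested number of internal knots per transition.
#' @return named list of [spline_spec()] objects (`t01`, `t02`, `t12`).
#' @export
default_specs <- function(records, m = 1L) {
  records <- subject_records(records)
  mids <- (records$l1 + records$t1) / 2
  p01 <- c(records$t1[records$d1 == 1 & records$exact == 1],
           mids[records$d1 == 1 & records$exact == 0])
  p02 <- records$t2[records$d2 == 1 & records$d1 == 0]
  p12 <- records$t2[records$d2 == 1 & records$d1 == 1]
  pool_death <- records$t2[records$d2 == 1]
  pool_all <- c(records$t1, records$t2)
  mk <- function(primary) {
    for (mm in rev(seq.int(0L, m))) {
      for (p in list(primary, pool_death, pool_all)) {
        sp <- tryCatch(place_knots(p, mm), error = function(e) NULL)
        if (!is.null(sp)) return(sp)
      }
    }
    stop("cannot place knots: too few distinct observation times", call. = FALSE)
  }
  list(t01 = mk(p01), t02 = mk(p02), t12 = mk(p12))
}

#' Maximum likelihood fit of the illness-death model
#'
#' Maximizes the interval-censored illness-death likelihood (see
#' [lik_contribution()]) over the stacked spline coefficients
#' \eqn{(\gamma_{01}, \gamma_{02}, \gamma_{12})} by BFGS with analytic
#' gradients. When no likelihood term involves the 1->2 transition (for
#' example, purely right-censored cause-specific data in which follow-up ends
#' at the first event) the 1->2 coefficients are held fixed at their initial
#' values and excluded from the optimization.
#'
#' @param records a [subject_records()] data frame (at least one observed
#'   event of interest recommended).
#' @param specs named list of three [spline_spec()] objects; defaults to
#'   [default_specs()] with `m` internal knots.
#' @param m number of internal knots per transition used when `specs` is
#'   `NULL`.
#' @param init optional initial coefficients (list as returned by
#'   [initial_values()] or a stacked numeric vector); defaults to
#'   [initial_values()].
#' @param nodes Gauss-Legendre node count for the likelihood integrals.
#' @param control list of optimizer settings: `maxit` (500), `reltol`
#'   (1e-10), `restarts` (1).
#' @param init_seed seed forwarded to [initial_values()].
#' @return An object of class `"idm_fit"`: `model`
#'   (an [illness_death_model()]), `loglik`, `convergence` (list with
#'   `converged`, `iterations`, `gradient_norm`), `specs`, `nodes`, `n`.
#' @export
fit_idm <- function(records, specs = NULL, m = 1L, init = NULL, nodes = 64L,
                    control = list(), init_seed = 1L) {
  records <- subject_records(records)
  if (is.null(specs)) specs <- default_specs(records, m)
  if (is.null(init)) init <- initial_values(records, specs, seed = init_seed)
  if (is.list(init)) init <- c(init$gamma01, init$gamma02, init$gamma12)
  p <- vapply(specs, function(s) s$dim, integer(1))
  if (length(init) != sum(p))
    stop("initial coefficient vector has wrong length", call. = FALSE)

  cache <- .build_cache(records, specs, nodes)
  active3 <- any(records$d1 == 1 & (records$t2 > records$t1 | records$d2 == 1)) ||
    any(records$d1 == 0 & records$l1 < records$t2)
  if (!is.finite(cpp_idm_loglik(cache, init, 0L))) {
    fb <- .exp_init(records, specs)
    init <- c(fb$gamma01, fb$gamma02, fb$gamma12)
  }
  res <- .fit_on_cache(cache, p, init, skip = 0L, active3 = active3,
                       control = control)
  structure(
    list(model = .unstack_gamma(res$par, specs),
         loglik = res$loglik,
         convergence = list(converged = res$converged,
                            iterations = res$iterations,
                            gradient_norm = res$gradient_norm),
         specs = specs, nodes = nodes, n = nrow(records),
         active12 = active3),
    class = "idm_fit")
}

#' @export
print.idm_fit <- function(x, ...) {
  cat(sprintf("Illness-death MLE: n = %d, log-likelihood = %.4f (%s, %d evals)\n",
              x$n, x$loglik,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  print(x$model)
  invisible(x)
}
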