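#' Full-sample cumulative incidence from the fitted illness-death model
#'
#' Fits the illness-death model by maximum likelihood and evaluates the
#' cumulative incidence of the event of interest at the requested times.
#'
#' @inheritParams fit_idm
#' @param eval_times positive evaluation times.
#' @return list with `theta` (named vector of cumulative incidence values),
#'   `fit` (the [fit_idm()] object).
#' @export
full_sample_cif <- function(records, eval_times, specs = NULL, m = 1L,
                            nodes = 64L, control = list(), init_seed = 1L) {
  fit <- fit_idm(records, specs = specs, m = m, nodes = nodes,
                 control = control, init_seed = init_seed)
  theta <- cumulative_incidence(eval_times, fit$model, nodes = nodes)
  list(theta = setNames(theta, paste0("t", eval_times)), fit = fit)
}

#' Jackknife pseudo-observations of the cumulative incidence
#'
#' Computes the full-sample estimate \eqn{\hat\theta(t)} and, for every
#' subject, the leave-one-out estimate \eqn{\hat\theta_{(-i)}(t)} obtained by
#' refitting the model without that subject (same spline knots, refit
#' warm-started at the full-sample coefficients), then forms the
#' pseudo-observations
#' \deqn{\theta_i(t) = n \hat\theta(t) - (n - 1) \hat\theta_{(-i)}(t).}
#' Pseudo-observations may legitimately fall outside \eqn{[0, 1]}; no
#' clipping is applied. If any leave-one-out refit fails to converge, the set
#' is flagged invalid (`valid = FALSE`) but all partial results are returned.
#'
#' @inheritParams full_sample_cif
#' @return Object of class `"pseudo_obs"`: `eval_times`, `theta_full`,
#'   `theta_loo` (n x times matrix), `pseudo` (n x times matrix), `n`, `ids`,
#'   `converged` (per-subject flags), `valid`, `fit`.
#' @export
pseudo_obs <- function(records, eval_times, specs = NULL, m = 1L,
                       nodes = 64L, control = list(), init_seed = 1L) {
  records <- subject_records(records)
  n <- nrow(records)
  if (n < 2L) stop("pseudo-observations require n >= 2", call. = FALSE)
  fit <- fit_idm(records, specs = specs, m = m, nodes = nodes,
                 control = control, init_seed = init_seed)
  specs <- fit$specs
  theta_full <- cumulative_incidence(eval_times, fit$model, nodes = nodes)

  cache <- .build_cache(records, specs, nodes)
  p <- vapply(specs, function(s) s$dim, integer(1))
  warm <- .stack_gamma(fit$model)

  act <- if (fit$active12) seq_len(sum(p)) else seq_len(p[1] + p[2])
  cholH <- tryCatch(chol(.nll_hessian(cache, warm, act = act)),
                    error = function(e) NULL)
  theta_loo <- matrix(NA_real_, n, length(eval_times))
  conv <- logical(n)
  for (i in seq_len(n)) {
    res <- if (!is.null(cholH)) {
      .loo_refit(cache, p, warm, cholH, skip = i, act = act,
                 active3 = fit$active12, control = control)
    } else {
      .fit_on_cache(cache, p, warm, skip = i, active3 = fit$active12,
                    control = control)
    }
    conv[i] <- res$converged
    theta_loo[i, ] <- cumulative_incidence(eval_times,
                                           .unstack_gamma(res$par, specs),
                                           nodes = nodes)
  }
  pseudo <- matrix(rep(n * theta_full, each = n), n) - (n - 1) * theta_loo
  structure(
    list(eval_times = eval_times,
         theta_full = setNames(theta_full, paste0("t", eval_times)),
         theta_loo = theta_loo, pseudo = pseudo,
         n = n, ids = records$id, converged = conv,
         valid = fit$convergence$converged && all(conv),
         fit = fit),
    class = "pseudo_obs")
}

#' @export
print.pseudo_obs <- function(x, ...) {
  cat(sprintf("Parametric pseudo-observations: n = %d, eval times: %s\n",
              x$n, paste(x$eval_times, collapse = ", ")))
  cat("  full-sample cumulative incidence:",
      paste(format(x$theta_full, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  leave-one-out refits converged: %d/%d%s\n",
              sum(x$converged), x$n,
              if (x$valid) "" else "  [INVALID SET]"))
  invisible(x)
}

#' Aalen-Johansen cumulative incidence (exact-data comparator)
#'
#' Non-parametric cause-1 cumulative incidence for exactly observed
#' (right-censored) competing-risks data, computed with
#' [survival::survfit()] on a multi-state factor. Interval-censored input is
#' rejected: this estimator applies only to exact data.
#'
#' @param records a [subject_records()] data frame in which every event of
#'   interest is exactly observed.
#' @param eval_times times at which to evaluate the step function.
#' @return list with `step` (data frame `time`, `cif`: the full step
#'   function) and `cif` (values at `eval_times`).
#' @export
aalen_johansen_cif <- function(records, eval_times = NULL) {
  records <- subject_records(records)
  if (any(records$d1 == 1 & records$exact == 0))
    stop("Aalen-Johansen requires exactly observed event times; ",
         "interval-censored records present", call. = FALSE)
  # first-event representation: time to whichever event comes first
  time <- ifelse(records$d1 == 1, records$t1, records$t2)
  state <- factor(ifelse(records$d1 == 1, "event",
                         ifelse(records$d2 == 1 & records$t2 <= time, "competing",
                                "censor")),
                  levels = c("censor", "event", "competing"))
  sf <- survival::survfit(survival::Surv(time, state) ~ 1)
  idx <- match("event", sf$states)
  step <- data.frame(time = sf$time, cif = sf$pstate[, idx])
  out <- list(step = step)
  if (!is.null(eval_times)) {
    cif_at <- vapply(eval_times, function(t) {
      i <- findInterval(t, step$time)
      if (i == 0) 0 else step$cif[i]
    }, numeric(1))
    out$cif <- setNames(cif_at, paste0("t", eval_times))
  }
  out
}

#' Write or read a pseudo-observation table
#'
#' Long-format delimited text with header `id,time,pseudo,converged`, one row
#' per subject and evaluation time.
#'
#' @param pseudo a [pseudo_obs()] object.
#' @param path file path.
#' @export
write_pseudo_table <- function(pseudo, path) {
  stopifnot(inherits(pseudo, "pseudo_obs"))
  tab <- data.frame(
    id = rep(pseudo$ids, times = length(pseudo$eval_times)),
    time = rep(pseudo$eval_times, each = pseudo$n),
    pseudo = as.vector(pseudo$pseudo),
    converged = rep(as.integer(pseudo$converged), times = length(pseudo$eval_times)))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pseudo_table
#' @export
read_pseudo_table <- function(path) {
  read.csv(path)
}
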