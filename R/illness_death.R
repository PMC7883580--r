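#' Transition model: spline coefficients for one transition
#'
#' One transition of the illness-death model, with log cumulative hazard
#' \eqn{\ln H(t) = s(\ln t; \gamma)} for the spline defined by `spec`.
#'
#' @param spec a [spline_spec()].
#' @param gamma coefficient vector of length `spec$dim`.
#' @return Object of class `"transition_model"`.
#' @export
transition_model <- function(spec, gamma) {
  stopifnot(inherits(spec, "spline_spec"))
  gamma <- as.numeric(gamma)
  if (length(gamma) != spec$dim)
    stop(sprintf("gamma must have length %d (basis dimension), got %d",
                 spec$dim, length(gamma)), call. = FALSE)
  structure(list(spec = spec, gamma = gamma), class = "transition_model")
}

#' Weibull transition as a spline model with no internal knots
#'
#' With no internal knots the basis is \eqn{[1, x]} and
#' \eqn{\gamma = (\ln k, b)} reproduces \eqn{H(t) = k t^b} exactly
#' (scale \eqn{k}, shape \eqn{b}). Boundary knots are irrelevant for the
#' basis in this case and default to a wide interval.
#'
#' @param scale Weibull scale \eqn{k > 0}.
#' @param shape Weibull shape \eqn{b > 0}.
#' @param boundary_knots log-time boundary knots for the (degenerate) spec.
#' @return A [transition_model()].
#' @export
weibull_transition <- function(scale, shape, boundary_knots = log(c(0.01, 100))) {
  stopifnot(scale > 0, shape > 0)
  transition_model(spline_spec(boundary_knots = boundary_knots),
                   c(log(scale), shape))
}

#' Illness-death model
#'
#' Three-state model with states 0 (event-free), 1 (event of interest has
#' occurred) and 2 (dead / competing event), and transitions 0->1, 0->2,
#' 1->2, each a [transition_model()].
#'
#' @param t01,t02,t12 [transition_model()] objects for the three transitions.
#' @return Object of class `"illness_death_model"`.
#' @export
illness_death_model <- function(t01, t02, t12) {
  for (tm in list(t01, t02, t12))
    stopifnot(inherits(tm, "transition_model"))
  structure(list(t01 = t01, t02 = t02, t12 = t12),
            class = "illness_death_model")
}

#' @export
print.illness_death_model <- function(x, ...) {
  cat("Illness-death model (log cumulative hazards: natural cubic splines in ln t)\n")
  for (nm in c("t01", "t02", "t12")) {
    tm <- x[[nm]]
    cat(sprintf("  %s: m = %d, gamma = (%s)\n", sub("t", "", nm),
                length(tm$spec$internal_knots),
                paste(format(tm$gamma, digits = 4), collapse = ", ")))
  }
  invisible(x)
}

.check_time <- function(t) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("time must be positive and finite", call. = FALSE)
}

#' Cumulative hazard, hazard, survival and cumulative incidence
#'
#' `cum_hazard()` returns \eqn{H(t) = \exp(s(\ln t; \gamma))} and
#' `trans_hazard()` the transition intensity
#' \eqn{h(t) = t^{-1} s'(\ln t;\gamma) \exp(s(\ln t;\gamma))}.
#' `event_free_survival()` returns \eqn{S(t) = \exp(-H_{01}(t) - H_{02}(t))}
#' and `cumulative_incidence()` the transition-specific cumulative incidence
#' \deqn{F_{0c}(t) = \int_0^t h_{0c}(u) S(u)\, du, \quad c \in \{1, 2\},}
#' by Gauss-Legendre quadrature after the substitution \eqn{u = t w^2}, which
#' removes the integrable endpoint singularity of Weibull-type hazards with
#' shape below one.
#'
#' Hazards are not constrained to be positive: a fitted spline that decreases
#' locally in \eqn{x} yields a negative intensity, and `trans_hazard()` warns
#' when this occurs (set `warn = FALSE` in inner loops).
#'
#' @param t positive time(s) on the natural scale.
#' @param tm a [transition_model()].
#' @param model an [illness_death_model()].
#' @param cause 1 for the event of interest (via \eqn{h_{01}}), 2 for the
#'   competing event (via \eqn{h_{02}}).
#' @param nodes number of quadrature nodes.
#' @param check if `TRUE`, recompute with twice the nodes and signal an error
#'   when the two results differ by more than `tol`.
#' @param tol quadrature self-consistency tolerance used when `check = TRUE`.
#' @param warn warn on negative hazard values.
#' @return numeric vector, one value per element of `t`.
#' @export
cum_hazard <- function(t, tm) {
  stopifnot(inherits(tm, "transition_model"))
  .check_time(t)
  drop(exp(ncs_basis(log(t), tm$spec) %*% tm$gamma))
}

#' @rdname cum_hazard
#' @export
trans_hazard <- function(t, tm, warn = TRUE) {
  stopifnot(inherits(tm, "transition_model"))
  .check_time(t)
  x <- log(t)
  s <- drop(ncs_basis(x, tm$spec) %*% tm$gamma)
  sp <- drop(ncs_basis_deriv(x, tm$spec) %*% tm$gamma)
  if (warn && any(sp < 0))
    warning("spline is locally decreasing: negative hazard values returned")
  sp * exp(s) / t
}

#' @rdname cum_hazard
#' @export
event_free_survival <- function(t, model) {
  stopifnot(inherits(model, "illness_death_model"))
  .check_time(t)
  exp(-cum_hazard(t, model$t01) - cum_hazard(t, model$t02))
}

#' @rdname cum_hazard
#' @export
cumulative_incidence <- function(t, model, cause = 1L, nodes = 64L,
                                 check = FALSE, tol = 1e-8) {
  stopifnot(inherits(model, "illness_death_model"), cause %in% c(1L, 2L))
  .check_time(t)
  tm <- if (cause == 1L) model$t01 else model$t02
  # map u = t w^p: below the lowest knot the spline is linear with slope
  # gamma_1, so h ~ u^{gamma_1 - 1}; p >= 2 / gamma_1 makes the transformed
  # integrand vanish at least linearly at the origin.
  b_tail <- tm$gamma[2]
  p <- min(max(2, 2 / max(b_tail, 0.05)), 50)
  quad <- function(nn) {
    gl <- gl_nodes(nn)
    vapply(t, function(ti) {
      u <- ti * gl$nodes^p
      sum(gl$weights * p * ti * gl$nodes^(p - 1) *
            trans_hazard(u, tm, warn = FALSE) * event_free_survival(u, model))
    }, numeric(1))
  }
  f <- quad(nodes)
  if (check) {
    f2 <- quad(2L * nodes)
    if (any(abs(f - f2) > tol))
      stop(sprintf("quadrature not converged: node-doubling changes the result by up to %.3g",
                   max(abs(f - f2))), call. = FALSE)
  }
  f
}

#' Serialize a fitted or constructed illness-death model
#'
#' Models are written as plain-text JSON: per transition the knot positions on
#' the natural time scale, the coefficient vector, and (when present)
#' convergence metadata. `read_idm()` reproduces the in-memory object exactly.
#'
#' @param model an [illness_death_model()].
#' @param path file path.
#' @param meta optional named list of metadata (e.g. a convergence report).
#' @export
write_idm <- function(model, path, meta = NULL) {
  stopifnot(inherits(model, "illness_death_model"))
  ser <- lapply(model[c("t01", "t02", "t12")], function(tm) {
    list(internal_knot_times = exp(tm$spec$internal_knots),
         boundary_knot_times = exp(tm$spec$boundary_knots),
         gamma = tm$gamma)
  })
  obj <- list(format = "icpseudo_idm", version = 1L, transitions = ser)
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_idm
#' @export
read_idm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "icpseudo_idm"))
    stop("not an icpseudo model file", call. = FALSE)
  tms <- lapply(obj$transitions, function(tr) {
    transition_model(
      spline_spec(internal_knots = log(as.numeric(tr$internal_knot_times)),
                  boundary_knots = log(as.numeric(tr$boundary_knot_times))),
      as.numeric(tr$gamma))
  })
  model <- illness_death_model(tms$t01, tms$t02, tms$t12)
  attr(model, "meta") <- obj$meta
  model
}
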