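#' Restricted cubic spline specification on the log-time scale
#'
#' Defines the knot set for one transition of the illness-death model. The
#' log cumulative hazard of a transition is modelled as
#' \deqn{s(x; \gamma) = \gamma_0 + \gamma_1 x + \gamma_2 v_1(x) + \dots +
#'   \gamma_{m+1} v_m(x), \quad x = \ln t,}
#' where each basis term
#' \deqn{v_j(x) = (x - \xi_j)_+^3 - \lambda_j (x - \xi_{min})_+^3 -
#'   (1 - \lambda_j)(x - \xi_{max})_+^3,}
#' with \eqn{\lambda_j = (\xi_{max} - \xi_j) / (\xi_{max} - \xi_{min})}, is a
#' natural cubic spline term: twice continuously differentiable and linear
#' outside the boundary knots. The basis dimension is \eqn{m + 2}.
#'
#' @param internal_knots numeric vector of internal knots \eqn{\xi_1 < \dots <
#'   \xi_m} on the log-time scale (may be empty).
#' @param boundary_knots length-2 numeric, \eqn{(\xi_{min}, \xi_{max})} on the
#'   log-time scale.
#' @return An object of class `"spline_spec"` with elements `internal_knots`,
#'   `boundary_knots`, `lambda` and `dim`.
#' @seealso [place_knots()], [ncs_basis()]
#' @export
#' @examples
#' sp <- spline_spec(internal_knots = 1, boundary_knots = c(0, 2))
#' sp$lambda   # 0.5
spline_spec <- function(internal_knots = numeric(), boundary_knots) {
  internal_knots <- as.numeric(internal_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L)
    stop("`boundary_knots` must have length 2", call. = FALSE)
  knots <- c(boundary_knots[1], internal_knots, boundary_knots[2])
  if (any(!is.finite(knots)))
    stop("knots must be finite on the log-time scale", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing: xi_min < xi_1 < ... < xi_max",
         call. = FALSE)
  lambda <- (boundary_knots[2] - internal_knots) /
    (boundary_knots[2] - boundary_knots[1])
  structure(
    list(internal_knots = internal_knots, boundary_knots = boundary_knots,
         lambda = lambda, dim = length(internal_knots) + 2L),
    class = "spline_spec"
  )
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Restricted cubic spline spec (log-time scale)\n")
  cat("  boundary knots:", format(x$boundary_knots, digits = 4), "\n")
  if (length(x$internal_knots))
    cat("  internal knots:", format(x$internal_knots, digits = 4), "\n")
  else cat("  no internal knots (Weibull-type: basis [1, x])\n")
  invisible(x)
}

#' Natural cubic spline basis and derivative
#'
#' Evaluates the basis \eqn{[1, x, v_1(x), \dots, v_m(x)]} (or its derivative
#' \eqn{[0, 1, v_1'(x), \dots, v_m'(x)]}) of a [spline_spec()] at log-time
#' values `x`. The derivative of each truncated-power term is
#' \eqn{v_j'(x) = 3(x-\xi_j)_+^2 - 3\lambda_j (x-\xi_{min})_+^2 -
#' 3(1-\lambda_j)(x-\xi_{max})_+^2}, so the basis is linear in \eqn{x} outside
#' the boundary knots.
#'
#' @param x numeric vector of log-time values.
#' @param spec a [spline_spec()].
#' @return numeric matrix, `length(x)` rows by `spec$dim` columns.
#' @export
ncs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  cpp_ncs_basis(as.numeric(x), spec$internal_knots, spec$boundary_knots)
}

#' @rdname ncs_basis
#' @export
ncs_basis_deriv <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  cpp_ncs_basis_deriv(as.numeric(x), spec$internal_knots, spec$boundary_knots)
}

#' Place spline knots from event-time proxies
#'
#' Boundary knots are set at the range of the log proxy times and `m` internal
#' knots at equally spaced quantiles of the log proxy times. For
#' interval-censored events the natural proxies are the interval midpoints
#' (the same midpoints used to initialize the likelihood maximization).
#'
#' @param times positive event-time proxies on the natural time scale.
#' @param m number of internal knots (>= 0).
#' @return A [spline_spec()].
#' @export
#' @examples
#' place_knots(exp(1:3), m = 1)   # knots at 1, 2, 3 on the log scale
place_knots <- function(times, m = 1L) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("proxy times must be positive and finite", call. = FALSE)
  ut <- sort(unique(times))
  if (length(ut) < m + 2L)
    stop(sprintf("need at least %d distinct proxy times for m = %d internal knots, got %d",
                 m + 2L, m, length(ut)), call. = FALSE)
  lx <- log(times)
  bk <- range(lx)
  ik <- if (m > 0L) unname(quantile(lx, probs = seq_len(m) / (m + 1))) else numeric()
  if (any(ik <= bk[1]) || any(ik >= bk[2]) || any(duplicated(ik)))
    stop("degenerate knot placement: ties in proxy times collapse the quantiles",
         call. = FALSE)
  spline_spec(internal_knots = ik, boundary_knots = bk)
}
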