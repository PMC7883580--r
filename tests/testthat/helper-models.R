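# Fixture builders shared across the test files.

# all-exponential illness-death model (unit shape, Weibull embedding)
expo_model <- function(l01 = 0.1, l02 = 0.1, l12 = 0.4) {
  illness_death_model(weibull_transition(l01, 1),
                      weibull_transition(l02, 1),
                      weibull_transition(l12, 1))
}

# the generative model of the simulation study, one arm
arm_model <- function(k = 0.06, b = 0.5, l02 = 0.1, l12 = 0.4) {
  illness_death_model(weibull_transition(k, b),
                      weibull_transition(l02, 1),
                      weibull_transition(l12, 1))
}

# one-row subject record
rec1 <- function(l1, t1, d1, exact, t2, d2, id = 1) {
  data.frame(id = id, l1 = l1, t1 = t1, d1 = d1, exact = exact,
             t2 = t2, d2 = d2)
}

# exact, censoring-free, competing-risk-free records: everyone has the event
exact_event_records <- function(times) {
  data.frame(id = seq_along(times), l1 = times, t1 = times, d1 = 1L,
             exact = 1L, t2 = times, d2 = 0L)
}

# quadrature-free oracle for the cumulative incidence of a Weibull 0->1 +
# exponential 0->2 model, via stats::integrate on the closed-form integrand
cif_oracle <- function(k, b, lam, t) {
  integrate(function(u) k * b * u^(b - 1) * exp(-k * u^b - lam * u),
            0, t, rel.tol = 1e-12)$value
}

# m = 0 spline specs for all three transitions (Weibull family)
m0_specs <- function() {
  s <- spline_spec(boundary_knots = log(c(0.01, 100)))
  list(t01 = s, t02 = s, t12 = s)
}
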