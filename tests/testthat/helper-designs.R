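# Shared fixtures: all built in code, no data files.

# Cardiovascular-trial style design: rare events, one constant-hazard and one
# increasing-hazard component, moderate positive association, first component
# fatal. Used throughout the suite and in the acceptance checks.
cardio_design <- function(rho = 0.3, HR_e2 = 0.67, beta_e2 = 2,
                          followup_time = 1, ...) {
  suppressMessages(tte_design(
    p0_e1 = 0.024, p0_e2 = 0.051,
    HR_e1 = 0.90, HR_e2 = HR_e2,
    beta_e1 = 1, beta_e2 = beta_e2,
    rho = rho, rho_type = "spearman", copula = "frank",
    case = 3, followup_time = followup_time,
    alpha = 0.025, power = 0.90, ...
  ))
}

# Simple proportional-hazards reference: exponential components, equal
# effects, independent -- the composite is exactly exponential with the same
# hazard ratio.
ph_design <- function(h = 0.7, p1 = 0.3, p2 = 0.4) {
  tte_design(p0_e1 = p1, p0_e2 = p2, HR_e1 = h, HR_e2 = h,
             beta_e1 = 1, beta_e2 = 1, rho = 0,
             alpha = 0.025, power = 0.90)
}

# Central finite differences of the copula cdf, the independent oracle for
# the analytic partial derivatives.
fd_partials <- function(u, v, model, h = 1e-6) {
  list(
    du = (copula_cdf(u + h, v, model) - copula_cdf(u - h, v, model)) / (2 * h),
    dv = (copula_cdf(u, v + h, model) - copula_cdf(u, v - h, model)) / (2 * h)
  )
}

expect_within <- function(value, target, tol) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", value, tol, target))
}
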