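# Binary composite endpoints: probabilities, attainability bounds, effect
# conversion, sample size, relative efficiency.

test_that("prob_cbe matches the closed form and the enumerated 2x2 table", {
  expect_equal(prob_cbe(0.3, 0.6, 0), 0.72)
  expect_equal(prob_cbe(0.4, 0, 0), 0.4) # degenerate second event
  # brute-force oracle: build the joint table from P(1,1) and read 1 - P(0,0)
  p1 <- 0.2; p2 <- 0.3; rho <- 0.5
  p11 <- p1 * p2 + rho * sqrt(p1 * 0.8 * p2 * 0.7)
  p00 <- 1 - p1 - p2 + p11
  expect_equal(prob_cbe(p1, p2, rho), 1 - p00, tolerance = 1e-14)
})

test_that("prob_cbe decreases strictly in rho and validates attainability", {
  for (p1 in c(0.2, 0.5)) {
    for (p2 in c(0.3, 0.6)) {
      b <- corr_bounds(p1, p2)
      rhos <- seq(b$lower + 0.01, b$upper - 0.01, length.out = 7)
      vals <- vapply(rhos, function(r) prob_cbe(p1, p2, r), numeric(1))
      expect_true(all(diff(vals) < 0))
    }
  }
  expect_error(prob_cbe(0.2, 0.3, 0.99), "attainability")
})

test_that("correlation bounds come from the extreme 2x2 tables", {
  b <- corr_bounds(0.3, 0.3)
  expect_equal(b$upper, 1, tolerance = 1e-12)
  # p1 + p2 < 1: lower bound simplifies to -sqrt(p1 p2 / (q1 q2))
  b <- corr_bounds(0.2, 0.3)
  expect_equal(b$lower, -sqrt(0.2 * 0.3 / (0.8 * 0.7)), tolerance = 1e-12)
  # grid-enumeration oracle: every valid joint cell maps inside the bounds,
  # and the extremes are attained at the Frechet cells
  p1 <- 0.2; p2 <- 0.7
  b <- corr_bounds(p1, p2)
  p11_lo <- max(0, p1 + p2 - 1); p11_hi <- min(p1, p2)
  for (p11 in seq(p11_lo, p11_hi, length.out = 41)) {
    r <- (p11 - p1 * p2) / sqrt(p1 * 0.8 * p2 * 0.3)
    expect_gte(r, b$lower - 1e-12)
    expect_lte(r, b$upper + 1e-12)
  }
  r_lo <- (p11_lo - p1 * p2) / sqrt(p1 * 0.8 * p2 * 0.3)
  r_hi <- (p11_hi - p1 * p2) / sqrt(p1 * 0.8 * p2 * 0.3)
  expect_equal(r_lo, b$lower, tolerance = 1e-12)
  expect_equal(r_hi, b$upper, tolerance = 1e-12)
})

test_that("apply_effect converts each scale and rejects out-of-range results", {
  expect_equal(apply_effect(0.5, 1, "or"), 0.5)
  expect_equal(apply_effect(0.2, 0.5, "rr"), 0.1)
  expect_equal(apply_effect(0.3, -0.1, "diff"), 0.2)
  expect_error(apply_effect(0.2, 0.9, "diff"), "invalid-effect")
  expect_error(apply_effect(0.5, 3, "rr"), "invalid-effect")
})

test_that("effectsize_cbe composes arm probabilities consistently on all scales", {
  # null effects: (diff, rr, or) = (0, 1, 1)
  d0 <- binary_design(0.2, 0.3, eff_e1 = 0, eff_e2 = 0,
                      effm_e1 = "diff", effm_e2 = "diff", rho = 0.2)
  e0 <- effectsize_cbe(d0)
  expect_equal(e0$effect_diff, 0, tolerance = 1e-14)
  expect_equal(e0$effect_rr, 1, tolerance = 1e-14)
  expect_equal(e0$effect_or, 1, tolerance = 1e-14)

  # independent relative-risk effects: closed-form composite RR
  d <- binary_design(0.2, 0.3, eff_e1 = 0.8, eff_e2 = 0.6,
                     effm_e1 = "rr", effm_e2 = "rr", rho = 0, effm_ce = "rr")
  e <- effectsize_cbe(d)
  rr_oracle <- (1 - (1 - 0.2 * 0.8) * (1 - 0.3 * 0.6)) /
    (1 - 0.8 * 0.7)
  expect_equal(e$effect_rr, rr_oracle, tolerance = 1e-12)

  # protective effects on both components: composite risk decreases
  expect_lt(e$effect_diff, 0)

  # the three scales are mutually consistent with the arm probabilities
  expect_equal(e$effect_rr, e$p_ce_arm1 / e$p_ce_arm0, tolerance = 1e-12)
  odds <- function(p) p / (1 - p)
  expect_equal(e$effect_or, odds(e$p_ce_arm1) / odds(e$p_ce_arm0),
               tolerance = 1e-12)
  expect_equal(e$effect_diff, e$p_ce_arm1 - e$p_ce_arm0, tolerance = 1e-12)
})

test_that("attainability is validated in both arms", {
  # effects push arm-1 probabilities where the correlation is impossible
  expect_error(
    binary_design(0.5, 0.5, eff_e1 = -0.45, eff_e2 = 0,
                  effm_e1 = "diff", effm_e2 = "diff", rho = 0.8),
    "arm 1")
})

test_that("samplesize_cbe reproduces the textbook two-proportion formulas", {
  d <- binary_design(0.2, 0.3, eff_e1 = -0.05, eff_e2 = -0.05,
                     effm_e1 = "diff", effm_e2 = "diff", rho = 0,
                     alpha = 0.025, beta = 0.2, unpooled = TRUE,
                     alpha_kind = "one.sided")
  ss <- samplesize_cbe(d)
  # independent oracle for the endpoint-1 design (unpooled difference)
  za <- qnorm(0.975); zb <- qnorm(0.8)
  p0 <- 0.2; p1 <- 0.15
  n_arm <- (za + zb)^2 * (p0 * 0.8 + p1 * 0.85) / (p1 - p0)^2
  expect_equal(ss$n_e1_raw, n_arm, tolerance = 1e-12)
  expect_equal(ss$n_e1, 2 * ceiling(n_arm))

  # halving the effect roughly quadruples the unpooled sample size
  d2 <- binary_design(0.2, 0.3, eff_e1 = -0.025, eff_e2 = -0.05,
                      effm_e1 = "diff", effm_e2 = "diff", rho = 0,
                      alpha = 0.025, beta = 0.2, alpha_kind = "one.sided")
  expect_within(samplesize_cbe(d2)$n_e1_raw / n_arm, 4, 0.25)

  # pooled and unpooled agree within 1% when the arms nearly coincide
  for (p0 in c(0.15, 0.4)) {
    du <- binary_design(p0, 0.3, eff_e1 = -0.002, eff_e2 = -0.05,
                        effm_e1 = "diff", effm_e2 = "diff", rho = 0,
                        unpooled = TRUE)
    dp <- binary_design(p0, 0.3, eff_e1 = -0.002, eff_e2 = -0.05,
                        effm_e1 = "diff", effm_e2 = "diff", rho = 0,
                        unpooled = FALSE)
    ratio <- samplesize_cbe(du)$n_e1_raw / samplesize_cbe(dp)$n_e1_raw
    expect_within(ratio, 1, 0.01)
  }
  expect_error(
    samplesize_cbe(binary_design(0.2, 0.3, eff_e1 = 0, eff_e2 = 0,
                                 effm_e1 = "diff", effm_e2 = "diff")),
    "infinite-sample-size")
})

test_that("binary ARE is the pre-rounding unpooled sample-size ratio", {
  # degenerate second component: ARE -> 1
  d <- binary_design(0.2, 1e-5, eff_e1 = -0.05, eff_e2 = -1e-6,
                     effm_e1 = "diff", effm_e2 = "diff", rho = 0)
  expect_within(are_cbe(d)$are, 1, 1e-3)

  # strong effect on the second, weak on the first: composite wins
  d2 <- binary_design(0.1, 0.2, eff_e1 = -0.01, eff_e2 = -0.10,
                      effm_e1 = "diff", effm_e2 = "diff", rho = 0)
  expect_gt(are_cbe(d2)$are, 1)

  # definitional equivalence with n_e1 / n_ce on a random design grid
  set.seed(2024)
  checked <- 0
  while (checked < 100) {
    p1 <- runif(1, 0.05, 0.5); p2 <- runif(1, 0.05, 0.5)
    e1 <- -runif(1, 0.005, p1 / 2); e2 <- -runif(1, 0.005, p2 / 2)
    rho <- runif(1, 0, 0.3)
    d <- tryCatch(
      binary_design(p1, p2, eff_e1 = e1, eff_e2 = e2,
                    effm_e1 = "diff", effm_e2 = "diff", rho = rho,
                    effm_ce = "diff", unpooled = TRUE),
      error = function(e) NULL)
    if (is.null(d)) next
    checked <- checked + 1
    a <- are_cbe(d)$are
    ss <- samplesize_cbe(d)
    expect_equal(a, ss$n_e1_raw / ss$n_composite_raw, tolerance = 1e-10)
    expect_equal(a > 1, ss$n_composite_raw < ss$n_e1_raw)
  }
})
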