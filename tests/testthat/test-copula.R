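# Copula families: closed forms, axioms, calibration, sampling.

theta_grid <- list(
  frank   = c(0.5, 2, 8),
  gumbel  = c(1.2, 2, 4),
  clayton = c(0.3, 2, 6)
)

test_that("copula cdf satisfies boundary margins and independence limits", {
  for (fam in names(theta_grid)) {
    for (th in theta_grid[[fam]]) {
      m <- copula_model(fam, th)
      u <- c(0, 0.17, 0.3, 0.85, 1)
      expect_equal(copula_cdf(u, rep(1, 5), m), u, tolerance = 1e-12)
      expect_equal(copula_cdf(rep(1, 5), u, m), u, tolerance = 1e-12)
      expect_equal(copula_cdf(u, rep(0, 5), m), rep(0, 5))
      expect_equal(copula_cdf(rep(0, 5), u, m), rep(0, 5))
    }
  }
  # independence limits return u*v
  expect_equal(copula_cdf(0.3, 0.6, copula_model("frank", 0)), 0.18)
  expect_equal(copula_cdf(0.3, 0.6, copula_model("clayton", 0)), 0.18)
  expect_equal(copula_cdf(0.3, 0.6, copula_model("gumbel", 1)), 0.18)
})

test_that("clayton closed form matches its generator expression", {
  m <- copula_model("clayton", 2)
  expect_equal(copula_cdf(0.5, 0.5, m), (0.5^-2 + 0.5^-2 - 1)^(-1 / 2),
               tolerance = 1e-14)
})

test_that("copula axioms hold on a grid for every family and theta", {
  g <- seq(0.02, 0.98, length.out = 50)
  for (fam in names(theta_grid)) {
    for (th in theta_grid[[fam]]) {
      m <- copula_model(fam, th)
      C <- outer(g, g, function(a, b) copula_cdf(a, b, m))
      # Frechet-Hoeffding bounds
      lowerb <- outer(g, g, function(a, b) pmax(a + b - 1, 0))
      upperb <- outer(g, g, function(a, b) pmin(a, b))
      expect_true(all(C >= lowerb - 1e-12))
      expect_true(all(C <= upperb + 1e-12))
      # 2-increasing: every grid rectangle has nonnegative C-volume
      vol <- C[-1, -1] - C[-1, -50] - C[-50, -1] + C[-50, -50]
      expect_true(all(vol >= -1e-12))
    }
  }
})

test_that("analytic partials agree with central finite differences", {
  pts <- list(c(0.4, 0.7), c(0.15, 0.3), c(0.8, 0.55))
  for (fam in names(theta_grid)) {
    m <- copula_model(fam, theta_grid[[fam]][2])
    for (p in pts) {
      an <- copula_partials(p[1], p[2], m)
      fd <- fd_partials(p[1], p[2], m)
      expect_within(an$du, fd$du, 1e-6)
      expect_within(an$dv, fd$dv, 1e-6)
      # exchangeability: dC/du at (a,b) == dC/dv at (b,a)
      sw <- copula_partials(p[2], p[1], m)
      expect_equal(an$du, sw$dv, tolerance = 1e-12)
    }
  }
  # independence limit
  pp <- copula_partials(0.4, 0.7, copula_model("frank", 0))
  expect_equal(pp$du, 0.7)
  expect_equal(pp$dv, 0.4)
  # boundary clamping warns rather than failing
  expect_warning(copula_partials(0, 0.5, copula_model("frank", 2)), "clamped")
})

test_that("kendall calibration uses the closed-form inversions", {
  expect_equal(copula_from_association(0.5, "kendall", "clayton")$theta, 2)
  expect_equal(copula_from_association(0.5, "kendall", "gumbel")$theta, 2)
  # round trips at 1e-6 for all families
  for (fam in c("frank", "gumbel", "clayton")) {
    for (tau in c(0.1, 0.35, 0.7)) {
      m <- copula_from_association(tau, "kendall", fam)
      expect_within(copula_kendall(m), tau, 1e-6)
    }
  }
})

test_that("spearman calibration round-trips through the quadrature", {
  for (fam in c("frank", "gumbel", "clayton")) {
    for (rho in c(0.1, 0.3, 0.6, 0.85)) {
      m <- copula_from_association(rho, "spearman", fam)
      expect_within(copula_spearman(m), rho, 1e-4)
    }
  }
})

test_that("invalid parameters and unattainable associations error", {
  expect_error(copula_model("gumbel", 0.5), "invalid-parameter")
  expect_error(copula_model("clayton", -1), "invalid-parameter")
  expect_error(copula_from_association(-0.2, "spearman", "frank"),
               "cannot be negative")
  expect_error(copula_from_association(1, "kendall", "frank"),
               "unattainable")
  expect_error(copula_from_association(0.999, "kendall", "frank"),
               "unattainable")
})

test_that("sampled pairs are reproducible and carry the right dependence", {
  m <- copula_from_association(0.4, "kendall", "frank")
  s1 <- copula_sample(1000, m, seed = 42)
  s2 <- copula_sample(1000, m, seed = 42)
  expect_identical(s1, s2)

  # empirical kendall tau of the target value within 3 SE
  n <- 4000
  se3 <- 3 * sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  s <- copula_sample(n, m, seed = 1)
  expect_within(cor(s$u, s$v, method = "kendall"), 0.4, se3)

  g <- copula_sample(n, copula_model("gumbel", 2), seed = 2)
  expect_within(cor(g$u, g$v, method = "kendall"), 0.5, se3)

  cl <- copula_sample(n, copula_model("clayton", 2), seed = 3)
  expect_within(cor(cl$u, cl$v, method = "kendall"), 0.5, se3)

  ind <- copula_sample(n, copula_model("frank", 0), seed = 4)
  expect_within(cor(ind$u, ind$v, method = "kendall"), 0, se3)
})

test_that("sampler margins are uniform (Kolmogorov-Smirnov)", {
  n <- 1e5
  crit3 <- 3 * 1.358 / sqrt(n) # 3x the 5% critical value
  for (fam in c("frank", "gumbel", "clayton")) {
    m <- copula_from_association(0.5, "spearman", fam)
    s <- copula_sample(n, m, seed = 11)
    expect_lt(suppressWarnings(ks.test(s$u, "punif"))$statistic, crit3)
    expect_lt(suppressWarnings(ks.test(s$v, "punif"))$statistic, crit3)
  }
})

test_that("monte-carlo spearman of calibrated frank pairs recovers the target", {
  m <- copula_from_association(0.3, "spearman", "frank")
  s <- copula_sample(1e6, m, seed = 5)
  r <- cor(s$u, s$v, method = "spearman")
  expect_within(r, 0.3, 3 / sqrt(1e6) * (1 - 0.3^2) * 3) # generous 3 SE
})
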