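#' Probability of a binary composite endpoint
#'
#' Probability that at least one of two correlated binary events occurs:
#' `P(e*) = p1 + p2 - [p1 p2 + rho * sqrt(p1 q1 p2 q2)]`, where `rho` is
#' Pearson's correlation between the two event indicators.
#'
#' @param p1,p2 Event probabilities, in `(0, 1)`.
#' @param rho Pearson correlation between the indicators; must lie within
#'   the attainability bounds of [corr_bounds()].
#' @return The composite probability.
#' @examples
#' prob_cbe(0.3, 0.6, 0)   # 1 - 0.7 * 0.4 = 0.72
#' @export
prob_cbe <- function(p1, p2, rho = 0) {
  chk_p01(p1, "p1", open = FALSE); chk_p01(p2, "p2", open = FALSE)
  if (p1 > 0 && p1 < 1 && p2 > 0 && p2 < 1) {
    b <- corr_bounds(p1, p2)
    if (rho < b$lower - 1e-12 || rho > b$upper + 1e-12) {
      stop(sprintf(
        "attainability: rho = %g outside the Frechet bounds [%.4f, %.4f] for (p1, p2) = (%g, %g).",
        rho, b$lower, b$upper, p1, p2), call. = FALSE)
    }
  }
  p1 + p2 - (p1 * p2 + rho * sqrt(p1 * (1 - p1) * p2 * (1 - p2)))
}

chk_p01 <- function(x, nm, open = TRUE) {
  bad <- !is.numeric(x) || length(x) != 1L || !is.finite(x) ||
    (if (open) x <= 0 || x >= 1 else x < 0 || x > 1)
  if (bad) stop(sprintf("`%s` must be a probability%s.", nm,
                        if (open) " strictly inside (0, 1)" else ""),
                call. = FALSE)
}

#' Attainability bounds for the correlation of two binary events
#'
#' The Frechet-Hoeffding bounds on the joint cell `P(1,1)` translated to
#' Pearson's correlation: with `q = 1 - p`,
#' `lower = (max(0, p1 + p2 - 1) - p1 p2) / sqrt(p1 q1 p2 q2)` and
#' `upper = (min(p1, p2) - p1 p2) / sqrt(p1 q1 p2 q2)`.
#'
#' @param p1,p2 Event probabilities strictly inside `(0, 1)`.
#' @return A list with `lower` and `upper`.
#' @export
corr_bounds <- function(p1, p2) {
  chk_p01(p1, "p1"); chk_p01(p2, "p2")
  q1 <- 1 - p1; q2 <- 1 - p2
  s <- sqrt(p1 * q1 * p2 * q2)
  list(lower = (max(0, p1 + p2 - 1) - p1 * p2) / s,
       upper = (min(p1, p2) - p1 * p2) / s)
}

#' Apply a treatment effect to a control-arm probability
#'
#' Converts an anticipated effect into the treated-arm event probability:
#' risk difference `p0 + eff`, relative risk `p0 * eff`, or odds ratio
#' `odds1 = eff * p0/q0` back-transformed.
#'
#' @param p0 Control-arm probability in `(0, 1)`.
#' @param eff Effect value on the scale given by `measure`.
#' @param measure `"diff"`, `"rr"` or `"or"`.
#' @return The treated-arm probability, guaranteed inside `(0, 1)`.
#' @export
apply_effect <- function(p0, eff, measure = c("diff", "rr", "or")) {
  measure <- match.arg(measure)
  chk_p01(p0, "p0")
  p1 <- switch(measure,
    diff = p0 + eff,
    rr = p0 * eff,
    or = {
      o <- eff * p0 / (1 - p0)
      o / (1 + o)
    }
  )
  if (!is.finite(p1) || p1 <= 0 || p1 >= 1) {
    stop(sprintf("invalid-effect: %s = %g maps p0 = %g outside (0, 1).",
                 measure, eff, p0), call. = FALSE)
  }
  p1
}

#' Binary composite endpoint design
#'
#' Design inputs for a two-arm trial whose primary endpoint is the
#' occurrence of either of two correlated binary events.
#'
#' @param p0_e1,p0_e2 Control-arm event probabilities, in `(0, 1)`.
#' @param eff_e1,eff_e2 Anticipated effects for each component.
#' @param effm_e1,effm_e2 Effect measure for each component: `"diff"`,
#'   `"rr"` or `"or"`.
#' @param rho Pearson correlation between the two event indicators, assumed
#'   common to both arms; validated against the attainability bounds of both
#'   arms.
#' @param effm_ce Effect measure requested for the composite (default
#'   `"diff"`).
#' @param alpha Type-I error probability. Interpreted per `alpha_kind`.
#' @param beta Type-II error probability (power is `1 - beta`).
#' @param unpooled Use the unpooled variance estimate on the difference
#'   scale (default `TRUE`); `FALSE` uses the pooled form.
#' @param alpha_kind `"two.sided"` (default) or `"one.sided"`, mirroring
#'   [tte_design()].
#' @return An object of class `binary_design`.
#' @export
binary_design <- function(p0_e1, p0_e2, eff_e1, eff_e2,
                          effm_e1 = c("diff", "rr", "or"),
                          effm_e2 = c("diff", "rr", "or"),
                          rho = 0, effm_ce = c("diff", "rr", "or"),
                          alpha = 0.05, beta = 0.20, unpooled = TRUE,
                          alpha_kind = c("two.sided", "one.sided")) {
  effm_e1 <- match.arg(effm_e1); effm_e2 <- match.arg(effm_e2)
  effm_ce <- match.arg(effm_ce)
  alpha_kind <- match.arg(alpha_kind)
  chk_p01(p0_e1, "p0_e1"); chk_p01(p0_e2, "p0_e2")
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5).", call. = FALSE)
  if (beta <= 0 || beta >= 0.5) stop("`beta` must lie in (0, 0.5).", call. = FALSE)

  p1_e1 <- apply_effect(p0_e1, eff_e1, effm_e1)
  p1_e2 <- apply_effect(p0_e2, eff_e2, effm_e2)
  for (arm in 0:1) {
    pa <- if (arm == 0) c(p0_e1, p0_e2) else c(p1_e1, p1_e2)
    b <- corr_bounds(pa[1], pa[2])
    if (rho < b$lower - 1e-12 || rho > b$upper + 1e-12) {
      stop(sprintf(
        "attainability: rho = %g violates the bounds [%.4f, %.4f] in arm %d.",
        rho, b$lower, b$upper, arm), call. = FALSE)
    }
  }
  structure(list(
    p0_e1 = p0_e1, p0_e2 = p0_e2,
    eff_e1 = eff_e1, eff_e2 = eff_e2,
    effm_e1 = effm_e1, effm_e2 = effm_e2,
    p1_e1 = p1_e1, p1_e2 = p1_e2,
    rho = rho, effm_ce = effm_ce,
    alpha = alpha, beta = beta, unpooled = isTRUE(unpooled),
    alpha_kind = alpha_kind
  ), class = "binary_design")
}

#' @export
print.binary_design <- function(x, ...) {
  cat("<binary_design>\n")
  cat(sprintf("  e1: p0 = %g, %s effect = %g\n", x$p0_e1, x$effm_e1, x$eff_e1))
  cat(sprintf("  e2: p0 = %g, %s effect = %g\n", x$p0_e2, x$effm_e2, x$eff_e2))
  cat(sprintf("  Pearson rho = %g; alpha = %g (%s), beta = %g, %s variance\n",
              x$rho, x$alpha, x$alpha_kind, x$beta,
              if (x$unpooled) "unpooled" else "pooled"))
  invisible(x)
}

#' Effect size of a binary composite endpoint
#'
#' Derives the treated-arm component probabilities from the anticipated
#' effects, the per-arm composite probabilities under the shared Pearson
#' correlation, and the composite effect expressed on all three scales.
#'
#' @param design A [binary_design()].
#' @return An object of class `cbe_effect` with per-arm composite
#'   probabilities and `effect_diff`, `effect_rr`, `effect_or` (the measure
#'   requested in the design is marked in `effm_ce`).
#' @export
effectsize_cbe <- function(design) {
  stopifnot(inherits(design, "binary_design"))
  p_ce0 <- prob_cbe(design$p0_e1, design$p0_e2, design$rho)
  p_ce1 <- prob_cbe(design$p1_e1, design$p1_e2, design$rho)
  odds <- function(p) p / (1 - p)
  structure(list(
    p_ce_arm0 = p_ce0, p_ce_arm1 = p_ce1,
    effect_diff = p_ce1 - p_ce0,
    effect_rr = p_ce1 / p_ce0,
    effect_or = odds(p_ce1) / odds(p_ce0),
    effm_ce = design$effm_ce
  ), class = "cbe_effect")
}

#' @export
print.cbe_effect <- function(x, ...) {
  cat("Binary composite endpoint effect\n")
  cat(sprintf("  P(e*) arm 0 = %.4f, arm 1 = %.4f\n", x$p_ce_arm0, x$p_ce_arm1))
  cat(sprintf("  risk difference = %.4f, relative risk = %.4f, odds ratio = %.4f  (requested: %s)\n",
              x$effect_diff, x$effect_rr, x$effect_or, x$effm_ce))
  invisible(x)
}

# Per-arm sample size for a two-proportion comparison on the given scale.
n_two_prop <- function(p0, p1, alpha, beta, scale, unpooled, alpha_kind) {
  za <- if (alpha_kind == "two.sided") stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  zb <- stats::qnorm(1 - beta)
  q0 <- 1 - p0; q1 <- 1 - p1
  if (abs(p1 - p0) < 1e-14) return(Inf)
  switch(scale,
    diff = {
      if (unpooled) {
        (za + zb)^2 * (p0 * q0 + p1 * q1) / (p1 - p0)^2
      } else {
        pb <- (p0 + p1) / 2; qb <- 1 - pb
        (za * sqrt(2 * pb * qb) + zb * sqrt(p0 * q0 + p1 * q1))^2 / (p1 - p0)^2
      }
    },
    rr = (za + zb)^2 * (q0 / p0 + q1 / p1) / log(p1 / p0)^2,
    or = {
      lor <- log(p1 / q1) - log(p0 / q0)
      (za + zb)^2 * (1 / (p0 * q0) + 1 / (p1 * q1)) / lor^2
    }
  )
}

#' Sample size for a binary composite endpoint
#'
#' Total sample sizes (both arms) for three competing designs: composite
#' endpoint as primary, first component only, second component only. The
#' composite comparison is carried out on the scale requested by `effm_ce`
#' (Wald variances on the log scale for relative risk and odds ratio);
#' each single-component design uses its own effect measure.
#'
#' @param design A [binary_design()].
#' @return An object of class `cbe_samplesize` with totals `n_composite`,
#'   `n_e1`, `n_e2` (each `2 x` per-arm, rounded up) and the raw per-arm
#'   values.
#' @export
samplesize_cbe <- function(design) {
  stopifnot(inherits(design, "binary_design"))
  eff <- effectsize_cbe(design)
  if (abs(eff$p_ce_arm1 - eff$p_ce_arm0) < 1e-14) {
    stop("infinite-sample-size: null composite effect.", call. = FALSE)
  }
  n_ce <- n_two_prop(eff$p_ce_arm0, eff$p_ce_arm1, design$alpha, design$beta,
                     design$effm_ce, design$unpooled, design$alpha_kind)
  n_e1 <- n_two_prop(design$p0_e1, design$p1_e1, design$alpha, design$beta,
                     design$effm_e1, design$unpooled, design$alpha_kind)
  n_e2 <- n_two_prop(design$p0_e2, design$p1_e2, design$alpha, design$beta,
                     design$effm_e2, design$unpooled, design$alpha_kind)
  tot <- function(x) if (is.finite(x)) 2 * ceiling(x) else x
  structure(list(
    n_composite = tot(n_ce), n_e1 = tot(n_e1), n_e2 = tot(n_e2),
    n_composite_raw = n_ce, n_e1_raw = n_e1, n_e2_raw = n_e2,
    scale_composite = design$effm_ce
  ), class = "cbe_samplesize")
}

#' @export
print.cbe_samplesize <- function(x, ...) {
  cat("Total sample size (balanced arms), binary endpoints\n")
  cat(sprintf("  composite (%s scale): %s\n", x$scale_composite,
              format(x$n_composite, big.mark = ",")))
  cat(sprintf("  endpoint 1 only: %s\n", format(x$n_e1, big.mark = ",")))
  cat(sprintf("  endpoint 2 only: %s\n", format(x$n_e2, big.mark = ",")))
  invisible(x)
}

#' Relative efficiency of the binary composite versus the relevant endpoint
#'
#' The squared ratio of the standardized (unpooled, difference-scale)
#' effects of the composite test and the first-component test, equal to the
#' pre-rounding sample-size ratio `n_e1 / n_composite` computed with
#' unpooled variances on the difference scale. Values above 1 favour the
#' composite endpoint.
#'
#' @param design A [binary_design()].
#' @return An object of class `cbe_are` with elements `are` and
#'   `recommendation`.
#' @export
are_cbe <- function(design) {
  stopifnot(inherits(design, "binary_design"))
  if (abs(design$p1_e1 - design$p0_e1) < 1e-14) {
    stop("undefined-ARE: null effect on the relevant endpoint.", call. = FALSE)
  }
  eff <- effectsize_cbe(design)
  std2 <- function(p0, p1) {
    (p1 - p0)^2 / (p0 * (1 - p0) + p1 * (1 - p1))
  }
  are <- std2(eff$p_ce_arm0, eff$p_ce_arm1) / std2(design$p0_e1, design$p1_e1)
  structure(list(
    are = are,
    recommendation = if (are > 1) "composite" else "relevant"
  ), class = "cbe_are")
}

#' @export
print.cbe_are <- function(x, ...) {
  cat(sprintf("ARE(binary composite vs relevant endpoint) = %.3f -> use the %s endpoint\n",
              x$are, x$recommendation))
  invisible(x)
}
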