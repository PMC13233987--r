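#' Law of the composite endpoint in one arm
#'
#' Derives the distribution of the time to the first of the two component
#' events, `T* = min(T1, T2)`, in a given arm. The control arm is fully
#' specified by the design: the joint survival is the copula evaluated at the
#' component survivals, `S*(t) = C_theta(S1(t), S2(t))`, the all-cause
#' density splits into the two cause-specific subdensities
#' `f*(t) = dC/du * f1(t) + dC/dv * f2(t)` evaluated at `(S1(t), S2(t))`, and
#' `lambda*(t) = f*(t)/S*(t)`. The treated arm is built by applying the
#' anticipated hazard ratios to the control arm's cause-specific hazards,
#' `lambda*1(t) = HR1 * lamC1(t) + HR2 * lamC2(t)`, and exponentiating the
#' cumulative hazard -- the construction under which the components' effects
#' act on cause-specific risk, as anticipated from previous trials.
#'
#' All functions operate on internal unit time `t` in `[0, 1]` (time in units
#' of the follow-up); multiply times by `design$followup_time` to recover the
#' user's scale.
#'
#' @param design A [tte_design()].
#' @param arm 0 (control) or 1 (treated).
#' @return An object of class `composite_law`: a list with vectorised
#'   functions `surv`, `dens`, `haz`, `cumhaz` on `[0, Inf)`, the probability
#'   `p_star_tau` of the composite event by the end of follow-up, and the
#'   cause-specific subdensity functions `dens_c1`, `dens_c2`.
#' @examples
#' d <- tte_design(p0_e1 = 0.1, p0_e2 = 0.2, HR_e1 = 0.8, HR_e2 = 0.7,
#'                 alpha = 0.025, power = 0.9)
#' cl0 <- composite_law(d, arm = 0)
#' cl0$p_star_tau
#' @export
composite_law <- function(design, arm = 0) {
  stopifnot(inherits(design, "tte_design"), arm %in% c(0, 1))
  core <- law_core(design)
  if (arm == 0) {
    out <- list(
      arm = 0L,
      surv = core$S0, dens = core$f0, haz = core$l0, cumhaz = core$L0,
      dens_c1 = core$fC1, dens_c2 = core$fC2,
      p_star_tau = 1 - core$S0(1)
    )
  } else {
    out <- list(
      arm = 1L,
      surv = core$S1, dens = core$f1, haz = core$l1, cumhaz = core$L1,
      dens_c1 = function(t) design$e1$HR * core$fC1(t) / core$S0(t) * core$S1(t),
      dens_c2 = function(t) design$e2$HR * core$fC2(t) / core$S0(t) * core$S1(t),
      p_star_tau = 1 - core$S1(1)
    )
  }
  structure(out, class = "composite_law")
}

#' @export
print.composite_law <- function(x, ...) {
  cat(sprintf("<composite_law> arm %d, P(T* <= tau) = %.4f\n",
              x$arm, x$p_star_tau))
  invisible(x)
}

# Internal engine shared by every operation on the time-to-event design.
# Returns vectorised closures for both arms on internal unit time.
law_core <- function(design) {
  b1 <- design$e1$shape; b2 <- design$e2$shape
  HR1 <- design$e1$HR; HR2 <- design$e2$HR
  sc1 <- scale_from_p0(design$e1$p0, b1, tau = 1)
  sc2 <- scale_from_p0(design$e2$p0, b2, tau = 1)
  cop <- design$copula
  eps <- .copula_eps

  S1m <- function(t) exp(-(t / sc1)^b1)
  S2m <- function(t) exp(-(t / sc2)^b2)
  f1m <- function(t) S1m(t) * (b1 / sc1) * (t / sc1)^(b1 - 1)
  f2m <- function(t) S2m(t) * (b2 / sc2) * (t / sc2)^(b2 - 1)

  S0 <- function(t) copula_cdf(pmin(pmax(S1m(t), eps), 1), pmin(pmax(S2m(t), eps), 1), cop)
  partials_at <- function(t) {
    u <- pmin(pmax(S1m(t), eps), 1 - eps)
    v <- pmin(pmax(S2m(t), eps), 1 - eps)
    copula_partials(u, v, cop)
  }
  fC1 <- function(t) partials_at(t)$du * f1m(t)
  fC2 <- function(t) partials_at(t)$dv * f2m(t)
  f0 <- function(t) {
    pp <- partials_at(t)
    pp$du * f1m(t) + pp$dv * f2m(t)
  }
  l0 <- function(t) f0(t) / S0(t)
  L0 <- function(t) -log(S0(t))

  # cause-1 cumulative hazard of the control composite; the cause-2 part is
  # recovered as L0 - LC1, so one quadrature per evaluation suffices
  LC1 <- function(t) {
    vapply(t, function(tt) {
      if (tt <= 0) return(0)
      stats::integrate(function(s) fC1(s) / S0(s), 0, tt,
                       abs.tol = 1e-10, rel.tol = 1e-9,
                       subdivisions = 400L)$value
    }, numeric(1))
  }
  l1 <- function(t) (HR1 * fC1(t) + HR2 * fC2(t)) / S0(t)
  L1 <- function(t) {
    lc1 <- LC1(t)
    HR2 * L0(t) + (HR1 - HR2) * lc1
  }
  S1 <- function(t) exp(-L1(t))
  f1 <- function(t) l1(t) * S1(t)

  list(S1m = S1m, S2m = S2m, f1m = f1m, f2m = f2m,
       sc1 = sc1, sc2 = sc2,
       S0 = S0, f0 = f0, l0 = l0, L0 = L0, fC1 = fC1, fC2 = fC2,
       l1 = l1, L1 = L1, S1 = S1, f1 = f1)
}

#' Time-varying hazard ratio of the composite endpoint
#'
#' The all-cause hazard ratio `HR*(t) = lambda*1(t) / lambda*0(t)` of the
#' composite endpoint, which is generally non-constant even when each
#' component obeys proportional hazards. `t = 0` is handled as a right limit:
#' when the component shapes differ, the component with the smaller shape
#' dominates the hazard at the origin and `HR*(0+)` equals its hazard ratio;
#' with equal shapes the limit is the hazard-weighted mix.
#'
#' @param design A [tte_design()].
#' @param t Time(s) in units of the follow-up (`[0, 1]` spans the trial).
#' @return `HR*(t)`, vectorised over `t`.
#' @examples
#' d <- tte_design(p0_e1 = 0.024, p0_e2 = 0.051, HR_e1 = 0.9, HR_e2 = 0.67,
#'                 beta_e1 = 1, beta_e2 = 2, rho = 0.3, case = 3,
#'                 alpha = 0.025, power = 0.9)
#' hr_star(d, c(0, 0.5, 1))
#' @export
hr_star <- function(design, t) {
  stopifnot(inherits(design, "tte_design"))
  core <- law_core(design)
  HR1 <- design$e1$HR; HR2 <- design$e2$HR
  b1 <- design$e1$shape; b2 <- design$e2$shape
  out <- numeric(length(t))
  zero <- t <= 0
  if (any(!zero)) {
    w1 <- core$fC1(t[!zero]); w2 <- core$fC2(t[!zero])
    out[!zero] <- (HR1 * w1 + HR2 * w2) / (w1 + w2)
  }
  if (any(zero)) {
    out[zero] <- if (b1 < b2) HR1 else if (b2 < b1) HR2 else {
      # equal shapes: both subhazards vanish/blow up at the same rate
      w1 <- b1 / core$sc1^b1; w2 <- b2 / core$sc2^b2
      (HR1 * w1 + HR2 * w2) / (w1 + w2)
    }
  }
  out
}

#' Survival curves of the components and the composite
#'
#' Tabulates, on a regular grid over the follow-up, the survival function of
#' each component and of the composite endpoint in both arms (six curves).
#' The treated-arm component curves are the proportional-hazards transforms
#' `S_k^(1) = (S_k^(0))^HR_k`; the treated-arm composite follows the
#' cause-specific construction of [composite_law()].
#'
#' @param design A [tte_design()].
#' @return A tibble with columns `time` (in the user's follow-up units),
#'   `arm`, `S_e1`, `S_e2`, `S_ce`.
#' @export
survival_curves <- function(design) {
  stopifnot(inherits(design, "tte_design"))
  core <- law_core(design)
  tt <- seq(0, 1, length.out = design$subdivisions)
  HR1 <- design$e1$HR; HR2 <- design$e2$HR
  out0 <- tibble::tibble(
    time = tt * design$followup_time, arm = 0L,
    S_e1 = core$S1m(tt), S_e2 = core$S2m(tt), S_ce = core$S0(tt)
  )
  out1 <- tibble::tibble(
    time = tt * design$followup_time, arm = 1L,
    S_e1 = core$S1m(tt)^HR1, S_e2 = core$S2m(tt)^HR2, S_ce = core$S1(tt)
  )
  out <- dplyr::bind_rows(out0, out1)
  class(out) <- c("cedesign_curves", class(out))
  out
}

# Find the median of a survival function by adaptive bracket doubling; the
# search extrapolates past the end of follow-up on the parametric law.
survival_median <- function(surv_fun, start = 1) {
  hi <- start
  for (i in 1:60) {
    val <- surv_fun(hi)
    if (!is.finite(val)) return(NA_real_)
    if (val < 0.5) break
    hi <- hi * 2
  }
  if (surv_fun(hi) >= 0.5) return(NA_real_)
  stats::uniroot(function(t) surv_fun(t) - 0.5, c(hi / 1024, hi),
                 extendInt = "downX", tol = 1e-10)$root
}
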