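#' Time-to-event composite endpoint design
#'
#' Collects every quantity needed to characterise a two-arm trial whose
#' primary endpoint is the time to the first of two events: per-component
#' control-arm event probabilities by the end of follow-up, anticipated
#' cause-specific hazard ratios, Weibull shapes, the association between the
#' component times, the competing-risk case, follow-up time and error rates.
#' Internally time is expressed in units of the follow-up (`tau = 1`);
#' `followup_time` only rescales reported time axes and time-denominated
#' outputs.
#'
#' @param p0_e1,p0_e2 Probability of observing each component event in the
#'   control arm by the end of follow-up, in `(0, 1)`. These are marginal
#'   probabilities: `p0_e1` is the probability of the first event even if the
#'   second had previously occurred, and vice versa.
#' @param HR_e1,HR_e2 Anticipated (cause-specific) hazard ratio for each
#'   component, `> 0`.
#' @param beta_e1,beta_e2 Weibull shape for each component (default 1,
#'   constant hazard).
#' @param rho Association between the two component times, in `[0, 1)`.
#' @param rho_type `"spearman"` (default) or `"kendall"`.
#' @param copula Copula family binding the component times: `"frank"`
#'   (default), `"gumbel"` or `"clayton"`.
#' @param case Competing-risk case, 1-4: 1 = neither component includes a
#'   fatal event, 2 = the second does, 3 = the first does, 4 = both do. The
#'   case governs the cross-censoring semantics of simulated data; it does
#'   not alter the law of the time to the first event.
#' @param followup_time Length of follow-up `tau` in any time unit
#'   (default 1).
#' @param alpha Type-I error probability (default 0.05). Interpreted
#'   according to `alpha_kind`.
#' @param power Power to detect the anticipated effect (default 0.80).
#' @param alpha_kind `"two.sided"` (default) uses the `alpha/2` normal
#'   quantile in the event-count formulas; `"one.sided"` uses the `alpha`
#'   quantile in the Schoenfeld form (the Freedman form always uses
#'   `alpha/2`). See the methods vignette for why two-sided is the default.
#' @param ss_formula `"schoenfeld"` (default) or `"freedman"`.
#' @param subdivisions Grid size for exported curve tables (default 1000).
#'   Numerical accuracy of the integrals is controlled separately by adaptive
#'   quadrature (absolute tolerance 1e-10).
#' @return An object of class `tte_design`.
#' @examples
#' d <- tte_design(
#'   p0_e1 = 0.024, p0_e2 = 0.051, HR_e1 = 0.90, HR_e2 = 0.67,
#'   beta_e1 = 1, beta_e2 = 2, rho = 0.3, case = 3,
#'   alpha = 0.025, power = 0.90
#' )
#' effectsize_tte(d)
#' @export
tte_design <- function(p0_e1, p0_e2, HR_e1, HR_e2,
                       beta_e1 = 1, beta_e2 = 1,
                       rho = 0.3, rho_type = c("spearman", "kendall"),
                       copula = c("frank", "gumbel", "clayton"),
                       case = 1, followup_time = 1,
                       alpha = 0.05, power = 0.80,
                       alpha_kind = c("two.sided", "one.sided"),
                       ss_formula = c("schoenfeld", "freedman"),
                       subdivisions = 1000) {
  rho_type <- match.arg(rho_type)
  copula <- match.arg(copula)
  alpha_kind <- match.arg(alpha_kind)
  ss_formula <- match.arg(ss_formula)

  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1) {
      stop(sprintf("`%s` must be a probability strictly inside (0, 1).", nm),
           call. = FALSE)
    }
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a positive number.", nm), call. = FALSE)
    }
  }
  chk_prob(p0_e1, "p0_e1"); chk_prob(p0_e2, "p0_e2")
  chk_pos(HR_e1, "HR_e1"); chk_pos(HR_e2, "HR_e2")
  chk_pos(beta_e1, "beta_e1"); chk_pos(beta_e2, "beta_e2")
  chk_pos(followup_time, "followup_time")
  if (!case %in% 1:4) stop("`case` must be 1, 2, 3 or 4.", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5).", call. = FALSE)
  if (power <= 0.5 || power >= 1) stop("`power` must lie in (0.5, 1).", call. = FALSE)
  if (subdivisions < 2) stop("`subdivisions` must be at least 2.", call. = FALSE)

  if (case != 1 && rho > 0) {
    # rank correlations are not identifiable from observed data when a
    # component is fatal; the design value must come from external knowledge
    message(sprintf(
      "Note: with case = %d, %s's correlation cannot be estimated from observed data in the presence of competing risks; rho = %g is taken as an external assumption.",
      case, if (rho_type == "spearman") "Spearman" else "Kendall", rho))
  }

  cop <- copula_from_association(rho, kind = rho_type, family = copula)

  structure(list(
    e1 = list(p0 = p0_e1, HR = HR_e1, shape = beta_e1),
    e2 = list(p0 = p0_e2, HR = HR_e2, shape = beta_e2),
    rho = rho, rho_type = rho_type, copula_family = copula,
    copula = cop, case = as.integer(case),
    followup_time = followup_time,
    alpha = alpha, power = power,
    alpha_kind = alpha_kind, ss_formula = ss_formula,
    subdivisions = as.integer(subdivisions)
  ), class = "tte_design")
}

#' @export
print.tte_design <- function(x, ...) {
  cat("<tte_design>\n")
  cat(sprintf("  e1: p0 = %g, HR = %g, shape = %g\n", x$e1$p0, x$e1$HR, x$e1$shape))
  cat(sprintf("  e2: p0 = %g, HR = %g, shape = %g\n", x$e2$p0, x$e2$HR, x$e2$shape))
  cat(sprintf("  association: %s %g (%s copula, theta = %.4g)\n",
              x$rho_type, x$rho, x$copula_family, x$copula$theta))
  cat(sprintf("  case %d, tau = %g, alpha = %g (%s), power = %g, %s formula\n",
              x$case, x$followup_time, x$alpha, x$alpha_kind, x$power,
              x$ss_formula))
  invisible(x)
}

# Internal: replace fields of a design, revalidating (used by sensitivity scan
# and the CLI).
update_tte_design <- function(design, ...) {
  args <- list(...)
  base <- list(
    p0_e1 = design$e1$p0, p0_e2 = design$e2$p0,
    HR_e1 = design$e1$HR, HR_e2 = design$e2$HR,
    beta_e1 = design$e1$shape, beta_e2 = design$e2$shape,
    rho = design$rho, rho_type = design$rho_type,
    copula = design$copula_family, case = design$case,
    followup_time = design$followup_time,
    alpha = design$alpha, power = design$power,
    alpha_kind = design$alpha_kind, ss_formula = design$ss_formula,
    subdivisions = design$subdivisions
  )
  base[names(args)] <- args
  do.call(tte_design, base)
}
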