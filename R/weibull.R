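#' Weibull marginal event-time law
#'
#' One component's event-time law in one arm, parameterised by shape `beta`
#' and scale `b` so that `S(t) = exp(-(t/b)^beta)`. Shapes below 1 give a
#' decreasing hazard over follow-up, 1 a constant hazard, above 1 an
#' increasing hazard.
#'
#' @param shape Weibull shape, `> 0` (dimensionless).
#' @param scale Weibull scale, `> 0` (time units).
#' @return An object of class `weibull_marginal` with vectorised `surv`,
#'   `dens`, `haz` functions and the parameters.
#' @export
weibull_marginal <- function(shape, scale) {
  stopifnot(is.numeric(shape), shape > 0, is.numeric(scale), scale > 0)
  structure(
    list(
      shape = shape, scale = scale,
      surv = function(t) exp(-(t / scale)^shape),
      dens = function(t) exp(-(t / scale)^shape) * (shape / scale) * (t / scale)^(shape - 1),
      haz  = function(t) (shape / scale) * (t / scale)^(shape - 1)
    ),
    class = "weibull_marginal"
  )
}

#' @export
print.weibull_marginal <- function(x, ...) {
  cat(sprintf("<weibull_marginal> shape = %g, scale = %g\n", x$shape, x$scale))
  invisible(x)
}

#' Weibull scale from a cumulative event probability
#'
#' Solves `1 - exp(-(tau/b)^beta) = p0` for the scale `b`, i.e.
#' `b = tau / (-log(1 - p0))^(1/beta)`, so the control-arm probability of the
#' event by the end of follow-up is matched exactly.
#'
#' @param p0 Event probability by time `tau`, strictly inside `(0, 1)`.
#' @param shape Weibull shape, `> 0`.
#' @param tau Follow-up time, `> 0`.
#' @return The scale parameter (same time units as `tau`).
#' @export
scale_from_p0 <- function(p0, shape, tau = 1) {
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) {
    stop("degenerate-probability: `p0` must lie strictly inside (0, 1).",
         call. = FALSE)
  }
  stopifnot(shape > 0, tau > 0)
  tau / (-log1p(-p0))^(1 / shape)
}

#' Treatment-arm marginal under a proportional hazards effect
#'
#' Applies a hazard ratio to a Weibull marginal: `S1(t) = S0(t)^HR`, which
#' within the Weibull family keeps the shape and rescales
#' `b1 = b0 * HR^(-1/beta)`.
#'
#' @param m0 A [weibull_marginal()] (control arm).
#' @param HR Hazard ratio, `> 0`.
#' @return A [weibull_marginal()] for the treated arm.
#' @export
arm1_marginal <- function(m0, HR) {
  stopifnot(inherits(m0, "weibull_marginal"), is.numeric(HR), HR > 0)
  weibull_marginal(shape = m0$shape, scale = m0$scale * HR^(-1 / m0$shape))
}
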