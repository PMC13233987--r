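#' Asymptotic relative efficiency of composite versus relevant endpoint
#'
#' Compares the efficiency of the logrank test based on the composite
#' endpoint against the test based on the first (most relevant) component
#' alone, as the squared ratio of their noncentrality parameters:
#'
#' `ARE = ( int_0^1 log(HR*(t)) f*0(t) dt )^2 /
#'        ( log(HR1)^2 * p*0(1) * p1_0(1) )`
#'
#' evaluated on time normalised to the unit follow-up. Whenever `ARE > 1`
#' the composite endpoint is the more efficient primary endpoint; otherwise
#' the relevant component should be preferred. The value can be roughly read
#' as the ratio of sample sizes required by the two designs for equal power.
#'
#' @param design A [tte_design()].
#' @return An object of class `tte_are` with elements `are` and
#'   `recommendation` (`"composite"` if `are > 1`, else `"relevant"`).
#' @examples
#' d <- tte_design(p0_e1 = 0.024, p0_e2 = 0.051, HR_e1 = 0.9, HR_e2 = 0.67,
#'                 beta_e1 = 1, beta_e2 = 2, rho = 0.3, case = 3,
#'                 alpha = 0.025, power = 0.9)
#' are_tte(d)
#' @export
are_tte <- function(design) {
  stopifnot(inherits(design, "tte_design"))
  if (abs(log(design$e1$HR)) < 1e-12) {
    stop("undefined-ARE: HR_e1 = 1 leaves the relevant-endpoint test with no effect to detect.",
         call. = FALSE)
  }
  core <- law_core(design)
  HR1 <- design$e1$HR; HR2 <- design$e2$HR
  log_hr <- function(t) {
    w1 <- core$fC1(t); w2 <- core$fC2(t)
    log((HR1 * w1 + HR2 * w2) / (w1 + w2))
  }
  num <- quad(function(t) log_hr(t) * core$f0(t))^2
  den <- log(HR1)^2 * (1 - core$S0(1)) * design$e1$p0
  are <- num / den
  structure(list(
    are = are,
    recommendation = if (are > 1) "composite" else "relevant"
  ), class = "tte_are")
}

#' @export
print.tte_are <- function(x, ...) {
  cat(sprintf("ARE(composite vs relevant endpoint) = %.2f -> use the %s endpoint\n",
              x$are, x$recommendation))
  invisible(x)
}
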