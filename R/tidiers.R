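#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a composite-endpoint effect summary
#'
#' @param x A `tte_effect` object.
#' @param ... Unused.
#' @return A tibble with one row per effect measure (`gAHR`, `AHR`,
#'   `median_ratio`, `RMST_ratio`) and its estimate.
#' @method tidy tte_effect
#' @export
tidy.tte_effect <- function(x, ...) {
  tibble::tibble(
    measure = c("gAHR", "AHR", "median_ratio", "RMST_ratio"),
    estimate = c(x$gAHR, x$AHR, x$mR, x$RMSTR)
  )
}

#' @rdname tidy.tte_effect
#' @method glance tte_effect
#' @export
glance.tte_effect <- function(x, ...) {
  tibble::tibble(
    gAHR = x$gAHR, AHR = x$AHR, median_ratio = x$mR, RMST_ratio = x$RMSTR,
    p_star_arm0 = x$p_star[["arm0"]], p_star_arm1 = x$p_star[["arm1"]],
    median_arm0 = x$median[["arm0"]], median_arm1 = x$median[["arm1"]],
    RMST_arm0 = x$RMST[["arm0"]], RMST_arm1 = x$RMST[["arm1"]],
    median_beyond_tau = any(x$median_beyond_tau)
  )
}

#' Tidy a composite-endpoint sample-size result
#'
#' @param x A `tte_samplesize` or `cbe_samplesize` object.
#' @param ... Unused.
#' @return A tibble with one row per candidate design (composite, each
#'   single component) and its total sample size.
#' @method tidy tte_samplesize
#' @export
tidy.tte_samplesize <- function(x, ...) {
  tibble::tibble(
    design = c("composite", "endpoint_1", "endpoint_2"),
    n_total = c(x$n_composite, x$n_e1, x$n_e2),
    n_total_raw = c(x$n_composite_raw, x$n_e1_raw, x$n_e2_raw)
  )
}

#' @rdname tidy.tte_samplesize
#' @method glance tte_samplesize
#' @export
glance.tte_samplesize <- function(x, ...) {
  tibble::tibble(
    n_composite = x$n_composite, n_e1 = x$n_e1, n_e2 = x$n_e2,
    events_composite = x$events_composite, gAHR = x$gAHR,
    p_star_avg = x$p_star_avg, formula = x$formula_used,
    noncentrality = x$noncentrality
  )
}

#' @rdname tidy.tte_samplesize
#' @method tidy cbe_samplesize
#' @export
tidy.cbe_samplesize <- function(x, ...) {
  tibble::tibble(
    design = c("composite", "endpoint_1", "endpoint_2"),
    n_total = c(x$n_composite, x$n_e1, x$n_e2),
    n_total_raw = c(2 * x$n_composite_raw, 2 * x$n_e1_raw, 2 * x$n_e2_raw)
  )
}

#' Tidy an endpoint-selection (relative efficiency) result
#'
#' @param x A `tte_are` or `cbe_are` object.
#' @param ... Unused.
#' @return A one-row tibble with the ARE value and the recommended primary
#'   endpoint.
#' @method tidy tte_are
#' @export
tidy.tte_are <- function(x, ...) {
  tibble::tibble(are = x$are, recommendation = x$recommendation)
}

#' @rdname tidy.tte_are
#' @method tidy cbe_are
#' @export
tidy.cbe_are <- tidy.tte_are

#' @rdname tidy.tte_effect
#' @method tidy cbe_effect
#' @export
tidy.cbe_effect <- function(x, ...) {
  tibble::tibble(
    measure = c("diff", "rr", "or"),
    estimate = c(x$effect_diff, x$effect_rr, x$effect_or),
    requested = c("diff", "rr", "or") == x$effm_ce
  )
}
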