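#' Simulate a two-arm trial with a time-to-event composite endpoint
#'
#' Generates latent component event times from the copula-bound Weibull
#' joint law of each arm (treated-arm marginals are the proportional-hazards
#' transforms of the control marginals), then applies non-informative
#' administrative right censoring at the end of follow-up and the
#' cross-censoring implied by the competing-risk case: a fatal component
#' censors the other component at its own occurrence. The composite columns
#' always record the first occurrence.
#'
#' Status coding is conventional survival coding: 1 = event observed,
#' 0 = censored. With `keep_latent = TRUE` the uncensored latent times are
#' kept in `latent_e1`, `latent_e2`, which supports dependence-recovery
#' checks that observed data cannot under competing risks.
#'
#' @param design A [tte_design()].
#' @param sample_size Participants per arm.
#' @param seed Optional integer seed; fixed seeds give identical output.
#' @param keep_latent Keep the latent (uncensored) component times.
#' @return A tibble of class `cedesign_trial` with columns `time_e1`,
#'   `status_e1`, `time_e2`, `status_e2`, `time_ce`, `status_ce`, `arm`
#'   (times in the user's follow-up units). The seed, if any, is stored in
#'   the `"seed"` attribute.
#' @examples
#' d <- tte_design(p0_e1 = 0.1, p0_e2 = 0.2, HR_e1 = 0.8, HR_e2 = 0.7,
#'                 alpha = 0.025, power = 0.9)
#' sim <- simula_tte(d, sample_size = 100, seed = 1)
#' table(sim$status_ce, sim$arm)
#' @export
simula_tte <- function(design, sample_size, seed = NULL, keep_latent = FALSE) {
  stopifnot(inherits(design, "tte_design"), sample_size >= 1)
  n <- as.integer(sample_size)
  if (!is.null(seed)) set.seed(as.integer(seed))
  b1 <- design$e1$shape; b2 <- design$e2$shape
  sc1 <- scale_from_p0(design$e1$p0, b1, tau = 1)
  sc2 <- scale_from_p0(design$e2$p0, b2, tau = 1)

  one_arm <- function(arm) {
    uv <- copula_sample(n, design$copula, seed = NULL)
    s1 <- if (arm == 1) sc1 * design$e1$HR^(-1 / b1) else sc1
    s2 <- if (arm == 1) sc2 * design$e2$HR^(-1 / b2) else sc2
    t1 <- s1 * (-log(uv$u))^(1 / b1)
    t2 <- s2 * (-log(uv$v))^(1 / b2)
    tau <- 1
    fatal1 <- design$case %in% c(3, 4)
    fatal2 <- design$case %in% c(2, 4)
    lim1 <- if (fatal2) pmin(t2, tau) else tau  # e2 fatal: censors e1
    lim2 <- if (fatal1) pmin(t1, tau) else tau  # e1 fatal: censors e2
    tibble::tibble(
      time_e1 = pmin(t1, lim1), status_e1 = as.integer(t1 <= lim1),
      time_e2 = pmin(t2, lim2), status_e2 = as.integer(t2 <= lim2),
      time_ce = pmin(t1, t2, tau), status_ce = as.integer(pmin(t1, t2) <= tau),
      arm = as.integer(arm),
      latent_e1 = t1, latent_e2 = t2
    )
  }
  out <- dplyr::bind_rows(one_arm(0), one_arm(1))
  scale_cols <- c("time_e1", "time_e2", "time_ce", "latent_e1", "latent_e2")
  out[scale_cols] <- lapply(out[scale_cols], function(x) x * design$followup_time)
  if (!keep_latent) out$latent_e1 <- out$latent_e2 <- NULL
  attr(out, "seed") <- seed
  class(out) <- c("cedesign_trial", class(out))
  out
}

#' Simulate a two-arm trial with a binary composite endpoint
#'
#' Draws each participant's pair of binary outcomes from the 2x2 joint law
#' with `P(1,1) = p1 p2 + rho * sqrt(p1 q1 p2 q2)` in each arm (treated-arm
#' probabilities obtained from the design effects) and records the composite
#' indicator `x_ce = max(x_e1, x_e2)`.
#'
#' @param design A [binary_design()].
#' @param sample_size Participants per arm.
#' @param seed Optional integer seed.
#' @return A tibble with columns `x_e1`, `x_e2`, `x_ce`, `arm`.
#' @export
simula_cbe <- function(design, sample_size, seed = NULL) {
  stopifnot(inherits(design, "binary_design"), sample_size >= 1)
  n <- as.integer(sample_size)
  if (!is.null(seed)) set.seed(as.integer(seed))
  one_arm <- function(arm) {
    p1 <- if (arm == 1) design$p1_e1 else design$p0_e1
    p2 <- if (arm == 1) design$p1_e2 else design$p0_e2
    p11 <- p1 * p2 + design$rho * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    probs <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
    if (any(probs < -1e-12)) {
      stop("attainability: rho incompatible with the arm probabilities.",
           call. = FALSE)
    }
    cell <- sample.int(4L, n, replace = TRUE, prob = pmax(probs, 0))
    x1 <- as.integer(cell %in% c(1L, 2L))
    x2 <- as.integer(cell %in% c(1L, 3L))
    tibble::tibble(x_e1 = x1, x_e2 = x2, x_ce = pmax(x1, x2),
                   arm = as.integer(arm))
  }
  out <- dplyr::bind_rows(one_arm(0), one_arm(1))
  attr(out, "seed") <- seed
  out
}

#' Write a simulated trial to CSV with a seed sidecar
#'
#' Writes the trial dataset with the canonical column order and a JSON
#' sidecar (`<path>.json`) recording the seed and generation parameters, so
#' a dataset on disk is always reproducible.
#'
#' @param sim Output of [simula_tte()] or [simula_cbe()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(sim, path) {
  cols <- intersect(c("time_e1", "status_e1", "time_e2", "status_e2",
                      "time_ce", "status_ce", "x_e1", "x_e2", "x_ce", "arm"),
                    names(sim))
  utils::write.csv(as.data.frame(sim)[cols], path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(seed = attr(sim, "seed"), rows = nrow(sim),
               columns = cols, written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
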