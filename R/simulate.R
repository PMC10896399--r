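# Synthetic cohort generator.
#
# Latent structure: one general-deficit factor plus one factor per domain
# (NI, SR, AF), all standard normal within subject. Each measure's oriented
# z-score is
#   z = mu[measure, group] + lg * general + ld * domain + age_slope * (age
#       - midpoint) + e,   e ~ N(0, sqrt(1 - lg^2 - ld^2))
# so that with the default loadings the marginal variance is exactly 1 and
# a per-group mean shift mu maps analytically onto the endorsement
# probability P(z <= -tau) = pnorm(-tau - mu). Calibration inverts that
# relation per criterion and group. z-scores are then written back on each
# measure's native scale (with orientation), and measures are masked
# missing-completely-at-random, re-drawing any subject left with an
# entirely unobserved domain.

#' Single-measure-per-criterion registry for simulation
#'
#' Twelve synthetic measures, one per criterion, on a mix of native scales
#' (IQ-type standard scores, problem-scale T-scores, scaled scores) so the
#' standardization layer is exercised. With one measure per criterion the
#' any-measure rule is the identity, which keeps the generator's
#' calibration analytic.
#'
#' @return An `ndpae_registry` with 12 rows.
#' @export
synth_registry <- function() {
  as_registry(rbind(
    reg_row("sim_iq",            "global_intellectual", "standard_100_15", "higher_better"),
    reg_row("sim_exec",          "executive_function",  "t_50_10",         "higher_worse"),
    reg_row("sim_learning",      "learning",            "scaled_10_3",     "higher_better"),
    reg_row("sim_memory",        "memory",              "scaled_10_3",     "higher_better"),
    reg_row("sim_visuospatial",  "visual_spatial",      "scaled_10_3",     "higher_better"),
    reg_row("sim_mood",          "mood_behavior",       "t_50_10",         "higher_worse"),
    reg_row("sim_attention",     "attention",           "t_50_10",         "higher_worse"),
    reg_row("sim_impulse",       "impulse_control",     "t_50_10",         "higher_worse"),
    reg_row("sim_communication", "communication",       "standard_100_15", "higher_better"),
    reg_row("sim_social",        "social",              "standard_100_15", "higher_better"),
    reg_row("sim_daily_living",  "daily_living",        "standard_100_15", "higher_better"),
    reg_row("sim_motor",         "motor",               "standard_100_15", "higher_better")
  ))
}

#' Configure the synthetic cohort generator
#'
#' Defaults reproduce the validation cohort's study conditions: group sizes
#' 486 (AE) and 679 (CON), per-criterion mean shifts calibrated to the
#' published 1.0-SD endorsement percentages, loadings 0.6 (general) / 0.4
#' (domain), 8% missingness per measure, ages uniform on 5-17, and the
#' published female proportions.
#'
#' @param n_ae,n_con Group sizes.
#' @param registry Measure registry for the simulated battery (default
#'   [synth_registry()]); must have exactly one measure per criterion when
#'   `mu` comes from [calibrate_to_rates()].
#' @param mu Numeric matrix (measures x 2, columns `AE`, `CON`) of
#'   per-measure mean shifts in oriented z units; default calibrated to the
#'   published 1.0-SD criterion rates via [calibrate_to_rates()].
#' @param loading_general,loading_domain Latent loadings `lg`, `ld`; must
#'   satisfy `lg^2 + ld^2 < 1`.
#' @param delta_general Named length-2 vector (`AE`, `CON`): additional
#'   group mean shift on the general factor, in z units. Default 0 (group
#'   separation is carried by `mu`).
#' @param p_missing Per-measure missing probability in `[0, 1)`.
#' @param age_slope Change in every measure's z per year of age (centered
#'   at 11y); default 0, set nonzero to induce an age effect on diagnosis.
#' @param p_female Named length-2 vector of female proportions per group.
#' @param age_range Length-2 vector, uniform age range in years.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_ae = 486L, n_con = 679L,
                         registry = synth_registry(),
                         mu = NULL,
                         loading_general = 0.6, loading_domain = 0.4,
                         delta_general = c(AE = 0, CON = 0),
                         p_missing = 0.08, age_slope = 0,
                         p_female = c(AE = 0.470, CON = 0.436),
                         age_range = c(5, 17), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_ae > 0L, n_con > 0L,
            is.finite(loading_general), is.finite(loading_domain),
            p_missing >= 0, p_missing < 1,
            length(age_range) == 2L, age_range[1] < age_range[2])
  registry <- as_registry(registry)
  if (any(registry$scale == "binary"))
    stop("the generator simulates continuous measures only")
  resid_var <- 1 - loading_general^2 - loading_domain^2
  if (resid_var <= 0)
    stop("loadings imply non-positive residual variance ",
         "(measure would have zero or negative noise variance)")
  if (is.null(mu)) {
    ref <- cifasd_reference()
    tr <- ref$criterion_rates[ref$criterion_rates$tau == 1.0, ]
    targets <- data.frame(criterion = tr$criterion,
                          AE = tr$AE / 100, CON = tr$CON / 100,
                          stringsAsFactors = FALSE)
    mu <- calibrated_mu(targets, tau = 1.0, registry = registry)
  }
  stopifnot(is.matrix(mu), nrow(mu) == nrow(registry),
            all(c("AE", "CON") %in% colnames(mu)), all(is.finite(mu)))
  rownames(mu) <- registry$measure_id
  structure(list(n_ae = as.integer(n_ae), n_con = as.integer(n_con),
                 registry = registry, mu = mu,
                 loading_general = loading_general,
                 loading_domain = loading_domain,
                 delta_general = delta_general,
                 resid_sd = sqrt(resid_var),
                 p_missing = p_missing, age_slope = age_slope,
                 p_female = p_female, age_range = age_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

calibrated_mu <- function(target_rates, tau, registry) {
  stopifnot(all(c("criterion", "AE", "CON") %in% names(target_rates)))
  p <- c(target_rates$AE, target_rates$CON)
  if (any(p <= 0 | p >= 1))
    stop("target rates must lie strictly inside (0, 1): ",
         "a rate of 0 or 1 has no finite mean shift")
  idx <- match(registry$criterion, target_rates$criterion)
  if (anyNA(idx))
    stop("no target rate for criterion: ",
         paste(registry$criterion[is.na(idx)], collapse = ", "))
  if (anyDuplicated(registry$criterion))
    stop("calibration requires one measure per criterion")
  # P(z <= -tau) = pnorm(-tau - mu)  =>  mu = -tau - qnorm(p)
  mu <- cbind(AE  = -tau - stats::qnorm(target_rates$AE[idx]),
              CON = -tau - stats::qnorm(target_rates$CON[idx]))
  rownames(mu) <- registry$measure_id
  mu
}

#' Calibrate generator mean shifts to target endorsement rates
#'
#' Inverse-probit calibration: with one measure per criterion and unit
#' marginal variance, the per-group measure mean `mu` that yields
#' endorsement probability `p` at threshold `tau` solves
#' `pnorm(-tau - mu) = p`, i.e. `mu = -tau - qnorm(p)`.
#'
#' @param target_rates Data frame with columns `criterion`, `AE`, `CON`
#'   (probabilities strictly inside (0, 1)).
#' @param tau Threshold (SD units) the targets refer to.
#' @param registry Single-measure-per-criterion registry, default
#'   [synth_registry()].
#' @param ... Further arguments passed to [synth_config()] (e.g. group
#'   sizes, `seed`).
#' @return A `synth_config` whose cohorts reproduce the targets in
#'   expectation.
#' @export
#' @examples
#' tr <- data.frame(criterion = ndpae_criteria()$criterion,
#'                  AE = 0.5, CON = 0.0228)
#' cfg <- calibrate_to_rates(tr, tau = 1, seed = 1)
#' cfg$mu[1, ]  # AE shift -1.0, CON shift about +1.0
calibrate_to_rates <- function(target_rates, tau, registry = synth_registry(),
                               ...) {
  registry <- as_registry(registry)
  mu <- calibrated_mu(target_rates, tau, registry)
  synth_config(registry = registry, mu = mu, ...)
}

native_from_z <- function(z, scale, orientation) {
  if (orientation == "higher_worse") z <- -z
  switch(scale,
         standard_100_15 = 100 + 15 * z,
         t_50_10         = 50 + 10 * z,
         scaled_10_3     = 10 + 3 * z,
         z               = z)
}

#' Generate a synthetic cohort
#'
#' Draws latent general and per-domain deficit factors for each subject,
#' builds oriented measure z-scores from the configured loadings and group
#' mean shifts, writes them back on each measure's native scale, and
#' applies missing-completely-at-random masking while guaranteeing every
#' subject keeps at least one observed measure per domain. Deterministic
#' given `config$seed`.
#'
#' @param config A `synth_config`.
#' @return An `ndpae_cohort` data frame (see [read_cohort()] for the
#'   layout), with `attr(, "config")` set.
#' @export
#' @examples
#' coh <- generate_cohort(synth_config(n_ae = 50, n_con = 50, seed = 1))
#' table(coh$group)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  reg <- config$registry
  n <- config$n_ae + config$n_con
  group <- rep(c("AE", "CON"), c(config$n_ae, config$n_con))
  doms <- criterion_domain(reg$criterion)
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
  sex <- ifelse(stats::runif(n) < config$p_female[group], "female", "male")
  g <- stats::rnorm(n) + config$delta_general[group]
  d <- matrix(stats::rnorm(3L * n), n, 3L,
              dimnames = list(NULL, c("NI", "SR", "AF")))
  age_mid <- mean(config$age_range)
  scores <- matrix(NA_real_, n, nrow(reg),
                   dimnames = list(NULL, reg$measure_id))
  for (j in seq_len(nrow(reg))) {
    z <- config$mu[j, group] +
      config$loading_general * g +
      config$loading_domain * d[, doms[j]] +
      config$age_slope * (age - age_mid) +
      stats::rnorm(n, sd = config$resid_sd)
    scores[, j] <- native_from_z(z, reg$scale[j], reg$orientation[j])
  }
  # MCAR mask with per-domain coverage guarantee
  if (config$p_missing > 0) {
    mask <- matrix(stats::runif(n * nrow(reg)) < config$p_missing,
                   n, nrow(reg))
    dom_cols <- split(seq_len(nrow(reg)), doms)
    bad_rows <- function(mk) {
      bad <- rep(FALSE, n)
      for (cols in dom_cols)
        bad <- bad | rowSums(!mk[, cols, drop = FALSE]) == 0L
      bad
    }
    bad <- bad_rows(mask)
    tries <- 0L
    while (any(bad)) {
      tries <- tries + 1L
      if (tries > 1000L) stop("could not satisfy domain coverage")
      mask[bad, ] <- stats::runif(sum(bad) * nrow(reg)) < config$p_missing
      bad <- bad_rows(mask)
    }
    scores[mask] <- NA_real_
  }
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    group = group, age = age, sex = sex,
                    site = "synthetic",
                    scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- as_cohort(out)
  attr(out, "config") <- config
  out
}
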