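# The ndpae() classifier fit: one call takes a cohort from raw scores to
# the threshold x model diagnosis grid, with methods for inspection,
# prediction on new subjects, and simulation of calibrated cohorts.

#' Apply the ND-PAE diagnostic criteria to a cohort
#'
#' Standardizes every registered score, codes the 12 criteria at each
#' requested impairment threshold, excludes subjects with an entirely
#' unobserved domain, and evaluates the domain logic under the requested
#' adaptive-functioning models. The result is a classed fit holding the
#' criterion matrices and the long-format diagnosis grid.
#'
#' @param data An `ndpae_cohort` data frame ([read_cohort()],
#'   [generate_cohort()]), or any data frame in that layout.
#' @param registry Measure registry covering all score columns in `data`.
#' @param tau Numeric vector of impairment thresholds (SD units); default
#'   `c(1, 1.5, 2)`.
#' @param models Subset of `c("AF2of4", "AF1", "hybridIQ")`. The hybrid
#'   model keeps the global-intellectual criterion at `hybrid_iq_tau`
#'   while coding everything else at 1.0 SD, and requires `1 %in% tau`.
#' @param hybrid_iq_tau IQ threshold for the hybrid model (default 2).
#' @return An object of class `ndpae`: a list with `cohort` (retained
#'   subjects), `registry`, `tau`, `models`, `matrices` (named list of
#'   `ndpae_cmat` per threshold), `hybrid_matrix`, `grid` (`ndpae_grid`),
#'   `exclusions` (log of dropped subjects), `n` (per-group retained
#'   counts), and `call`.
#' @seealso [summary.ndpae()], [predict.ndpae()], [simulate.ndpae()],
#'   [endorsement_rates()], [confusion_metrics()]
#' @export
#' @examples
#' coh <- generate_cohort(synth_config(n_ae = 120, n_con = 150, seed = 7))
#' fit <- ndpae(coh, registry = synth_registry())
#' fit
ndpae <- function(data, registry = ndpae_registry(), tau = c(1, 1.5, 2),
                  models = c("AF2of4", "AF1", "hybridIQ"),
                  hybrid_iq_tau = 2) {
  cl <- match.call()
  data <- as_cohort(as.data.frame(data))
  registry <- as_registry(registry)
  models <- match.arg(models, .models, several.ok = TRUE)
  stopifnot(is.numeric(tau), length(tau) >= 1L, all(tau > 0),
            !anyDuplicated(tau))
  if ("hybridIQ" %in% models && !1 %in% tau)
    stop("hybridIQ model requires tau = 1 among the thresholds")
  # domain coverage does not depend on tau: run exclusions once
  first <- criterion_matrix(data, registry, tau = tau[1])
  excl <- apply_exclusions(first)
  kept <- !data$subject_id %in% excl$log$subject_id
  cohort <- as_cohort(data[kept, , drop = FALSE])
  cmats <- lapply(tau, function(t)
    criterion_matrix(cohort, registry, tau = t))
  names(cmats) <- as.character(tau)
  hybrid <- NULL
  if ("hybridIQ" %in% models)
    hybrid <- criterion_matrix(cohort, registry, tau = 1,
                               iq_tau = hybrid_iq_tau)
  grid <- diagnosis_grid(cmats, models = models, hybrid_cmat = hybrid)
  structure(list(cohort = cohort, registry = registry, tau = tau,
                 models = models, matrices = cmats,
                 hybrid_matrix = hybrid, grid = grid,
                 exclusions = excl$log,
                 n = c(AE = sum(cohort$group == "AE"),
                       CON = sum(cohort$group == "CON")),
                 call = cl),
            class = "ndpae")
}

#' @export
print.ndpae <- function(x, ...) {
  cat("ND-PAE criterion classification\n")
  cat("  cohort   :", x$n[["AE"]], "AE /", x$n[["CON"]], "CON retained;",
      nrow(x$exclusions), "excluded (missing domain)\n")
  cat("  thresholds:", paste(x$tau, collapse = ", "), "SD;",
      "models:", paste(x$models, collapse = ", "), "\n")
  dg <- x$grid[x$grid$tau == min(x$tau), ]
  for (m in unique(dg$model)) {
    sl <- dg[dg$model == m, ]
    cat(sprintf("  %-8s @%.1f SD: ND-PAE %.1f%% AE, %.1f%% CON\n",
                m, min(x$tau),
                100 * mean(sl$ndpae[sl$group == "AE"]),
                100 * mean(sl$ndpae[sl$group == "CON"])))
  }
  invisible(x)
}

#' Summarize an ND-PAE fit
#'
#' Endorsement tables (criterion, domain, diagnosis), group contrasts
#' (uncorrected Pearson chi-square on the diagnosis-by-group table for each
#' threshold and model), and classification metrics against exposure group.
#'
#' @param object An `ndpae` fit.
#' @param ... Unused.
#' @return A list of class `summary.ndpae`: `rates` (see
#'   [endorsement_rates()]), `contrasts`, `classification`, `n`.
#' @export
summary.ndpae <- function(object, ...) {
  rates <- endorsement_rates(object)
  combos <- unique(object$grid[, c("tau", "model")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    tau <- combos$tau[i]; model <- combos$model[i]
    sl <- object$grid[object$grid$tau == tau & object$grid$model == model, ]
    tab <- rbind(AE  = c(sum(sl$ndpae[sl$group == "AE"]),
                         sum(!sl$ndpae[sl$group == "AE"])),
                 CON = c(sum(sl$ndpae[sl$group == "CON"]),
                         sum(!sl$ndpae[sl$group == "CON"])))
    chi <- tryCatch(chi_square_2x2(tab), error = function(e) NULL)
    cm <- confusion_metrics(object$grid, tau, model)
    data.frame(tau = tau, model = model,
               chisq = if (is.null(chi)) NA_real_ else chi$statistic,
               p = if (is.null(chi)) NA_real_ else chi$p.value,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               accuracy = cm$accuracy, stringsAsFactors = FALSE)
  })
  out <- list(rates = rates, contrasts = do.call(rbind, rows),
              n = object$n)
  class(out) <- "summary.ndpae"
  out
}

#' @export
print.summary.ndpae <- function(x, ...) {
  cat("ND-PAE validation summary (", x$n[["AE"]], "AE /", x$n[["CON"]],
      "CON )\n\nDiagnosis endorsement (% by group):\n")
  print(transform(x$rates$diagnosis, AE = round(AE, 1),
                  CON = round(CON, 1)), row.names = FALSE)
  cat("\nGroup contrasts and classification:\n")
  ct <- x$contrasts
  ct[c("chisq", "sensitivity", "specificity", "accuracy")] <-
    lapply(ct[c("chisq", "sensitivity", "specificity", "accuracy")],
           round, 1)
  ct$p <- signif(ct$p, 3)
  print(ct, row.names = FALSE)
  invisible(x)
}

#' Classify new subjects with a fitted rule set
#'
#' Applies the fit's registry and diagnostic logic to new cohort rows.
#'
#' @param object An `ndpae` fit.
#' @param newdata Cohort-layout data frame.
#' @param tau Threshold to classify at (default the fit's smallest).
#' @param model Adaptive-functioning model (default first of the fit's).
#' @param ... Unused.
#' @return A data frame: `subject_id`, `ni`, `sr`, `af`, `ndpae`.
#' @export
predict.ndpae <- function(object, newdata, tau = min(object$tau),
                          model = object$models[1], ...) {
  model <- match.arg(model, .models)
  newdata <- as_cohort(as.data.frame(newdata))
  if (model == "hybridIQ") {
    cmat <- criterion_matrix(newdata, object$registry, tau = 1,
                             iq_tau = attr(object$hybrid_matrix,
                                           "iq_tau") %||% 2)
    grid <- diagnosis_grid(list("1" = cmat), models = "hybridIQ",
                           hybrid_cmat = cmat)
  } else {
    cmat <- criterion_matrix(newdata, object$registry, tau = tau)
    grid <- diagnosis_grid(stats::setNames(list(cmat), as.character(tau)),
                           models = model)
  }
  grid[, c("subject_id", "ni", "sr", "af", "ndpae")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot endorsement profiles of an ND-PAE fit
#'
#' Diagnosis endorsement (percent) against the impairment threshold, one
#' line per group and model, on base graphics.
#'
#' @param x An `ndpae` fit.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ndpae <- function(x, ...) {
  rates <- endorsement_rates(x)$diagnosis
  rates <- rates[order(rates$model, rates$tau), ]
  models <- unique(rates$model)
  taus <- sort(unique(rates$tau))
  y <- sapply(models, function(m) {
    sl <- rates[rates$model == m, ]
    rbind(AE = sl$AE[match(taus, sl$tau)],
          CON = sl$CON[match(taus, sl$tau)])
  }, simplify = "array")
  ym <- matrix(aperm(y, c(2, 1, 3)), nrow = length(taus))
  graphics::matplot(taus, ym, type = "b", pch = rep(c(19, 1),
                                                    each = length(taus)),
                    lty = rep(seq_along(models), each = 2),
                    col = rep(seq_along(models), each = 2),
                    xlab = "impairment threshold (SD below mean)",
                    ylab = "% classified ND-PAE", ylim = c(0, 100), ...)
  graphics::legend("topright", bty = "n",
                   legend = as.vector(outer(c("AE", "CON"), models,
                                            function(g, m)
                                              paste(m, g, sep = ", "))),
                   col = rep(seq_along(models), each = 2),
                   pch = rep(c(19, 1), times = length(models)),
                   lty = rep(seq_along(models), each = 2))
  invisible(x)
}

#' Simulate cohorts calibrated to a fitted cohort's endorsement rates
#'
#' Calibrates the latent-factor generator to the per-criterion endorsement
#' rates observed in the fit at threshold `tau` (clamped away from 0 and 1
#' by half a count where necessary) and draws `nsim` synthetic cohorts of
#' the same group sizes.
#'
#' @param object An `ndpae` fit.
#' @param nsim Number of cohorts.
#' @param seed Integer seed (mandatory).
#' @param tau Threshold whose observed rates are used (default smallest).
#' @param ... Passed to [synth_config()] (e.g. `p_missing`).
#' @return A list of `ndpae_cohort` data frames of length `nsim`.
#' @export
simulate.ndpae <- function(object, nsim = 1, seed, tau = min(object$tau),
                           ...) {
  if (missing(seed)) stop("seed is mandatory")
  cr <- endorsement_rates(object)$criteria
  cr <- cr[cr$tau == tau, ]
  clamp <- function(p, n) pmin(pmax(p / 100, 0.5 / n), 1 - 0.5 / n)
  targets <- data.frame(criterion = cr$criterion,
                        AE = clamp(cr$AE, cr$n_AE),
                        CON = clamp(cr$CON, cr$n_CON),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nsim), function(i) {
    cfg <- calibrate_to_rates(targets, tau = tau,
                              n_ae = object$n[["AE"]],
                              n_con = object$n[["CON"]],
                              seed = seed + i - 1L, ...)
    generate_cohort(cfg)
  })
}
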