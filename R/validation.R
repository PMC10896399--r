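# Group contrasts, classification metrics, ROC, and the age/sex logistic
# model.

#' Endorsement percentages by group
#'
#' Per-criterion, per-domain, and per-diagnosis endorsement percentages by
#' group, threshold, and model. Percentages are 100 x endorsed / evaluable;
#' for criteria, subjects with the criterion unobserved are excluded from
#' the denominator, and a cell with zero evaluable subjects is `NaN` rather
#' than 0.
#'
#' @param fit An `ndpae` fit (see [ndpae()]).
#' @return A list of data frames `criteria` (`criterion`, `tau`, `AE`,
#'   `CON`, `n_AE`, `n_CON`), `domains` and `diagnosis` (`model`, `tau`,
#'   `AE`, `CON`).
#' @export
endorsement_rates <- function(fit) {
  stopifnot(inherits(fit, "ndpae"))
  grp <- function(g) factor(g, levels = c("AE", "CON"))
  crit_rows <- list()
  for (nm in names(fit$matrices)) {
    cmat <- fit$matrices[[nm]]
    g <- grp(attr(cmat, "group"))
    for (crit in colnames(cmat)) {
      v <- cmat[, crit]
      n_eval <- tapply(!is.na(v), g, sum)
      n_end <- tapply(v == 1L, g, sum, na.rm = TRUE)
      pct <- ifelse(n_eval > 0, 100 * n_end / n_eval, NaN)
      crit_rows[[length(crit_rows) + 1L]] <- data.frame(
        criterion = crit, tau = as.numeric(nm),
        AE = pct[["AE"]], CON = pct[["CON"]],
        n_AE = n_eval[["AE"]], n_CON = n_eval[["CON"]],
        stringsAsFactors = FALSE)
    }
  }
  grid <- fit$grid
  agg <- function(flag) {
    df <- data.frame(model = grid$model, tau = grid$tau,
                     group = grid$group, flag = flag,
                     stringsAsFactors = FALSE)
    out <- stats::aggregate(flag ~ model + tau + group, data = df,
                            FUN = mean)
    out$flag <- 100 * out$flag
    w <- stats::reshape(out, idvar = c("model", "tau"), timevar = "group",
                        direction = "wide")
    names(w) <- sub("^flag\\.", "", names(w))
    w
  }
  dom_rows <- list()
  for (d in c("ni", "sr", "af")) {
    w <- agg(grid[[d]])
    w$domain <- toupper(d)
    dom_rows[[d]] <- w[, c("domain", "model", "tau", "AE", "CON")]
  }
  domains <- do.call(rbind, dom_rows)
  rownames(domains) <- NULL
  diag_w <- agg(grid$ndpae)
  diagnosis <- diag_w[, c("model", "tau", "AE", "CON")]
  rownames(diagnosis) <- NULL
  list(criteria = do.call(rbind, crit_rows), domains = domains,
       diagnosis = diagnosis)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Reconstruct a 2x2 table from group percentages
#'
#' Converts published endorsement percentages and group sizes back into
#' integer counts (round half away from zero), giving the contingency table
#' the corresponding chi-square contrast was computed from.
#'
#' @param p1,n1 Percent endorsed and size of group 1 (rows: groups;
#'   columns: endorsed / not endorsed).
#' @param p2,n2 Percent endorsed and size of group 2.
#' @return A 2x2 integer matrix.
#' @export
#' @examples
#' counts_from_rates(69.2, 486, 22.6, 679)
counts_from_rates <- function(p1, n1, p2, n2) {
  stopifnot(p1 >= 0, p1 <= 100, p2 >= 0, p2 <= 100)
  a <- round_half_away(p1 * n1 / 100)
  c_ <- round_half_away(p2 * n2 / 100)
  matrix(as.integer(c(a, n1 - a, c_, n2 - c_)), nrow = 2L, byrow = TRUE,
         dimnames = list(group = c("g1", "g2"),
                         endorsed = c("yes", "no")))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson chi-square, `N (ad - bc)^2` over the product of the
#' four margins, with 1 degree of freedom. No continuity correction is
#' applied (the published contrasts reproduce only without it).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return A list: `statistic`, `df` (1), `p.value`, `n`.
#' @export
#' @examples
#' chi_square_2x2(counts_from_rates(69.2, 486, 22.6, 679))
chi_square_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  n <- sum(tab)
  if (n <= 0) stop("empty table")
  margins <- c(rowSums(tab), colSums(tab))
  if (any(margins == 0)) stop("zero margin: chi-square undefined")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  stat <- n * (a * d - b * c_)^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE), n = n)
}

#' Sensitivity, specificity, and accuracy of group classification
#'
#' Treats the ND-PAE classification as a predictor of exposure group:
#' sensitivity is the percent of AE subjects classified ND-PAE, specificity
#' the percent of CON subjects classified not ND-PAE, and accuracy the
#' prevalence-weighted combination
#' `(sens * n_AE + spec * n_CON) / (n_AE + n_CON)`.
#'
#' @param grid An `ndpae_grid` (see [diagnosis_grid()]).
#' @param tau,model Threshold and model selecting one grid slice.
#' @return A list: `sensitivity`, `specificity`, `accuracy` (percent),
#'   `n_ae`, `n_con`.
#' @export
confusion_metrics <- function(grid, tau, model) {
  sl <- grid[grid$tau == tau & grid$model == model, ]
  if (!nrow(sl)) stop("no grid rows for tau = ", tau, ", model = ", model)
  ae <- sl$group == "AE"
  n_ae <- sum(ae); n_con <- sum(!ae)
  if (n_ae == 0L || n_con == 0L) stop("both groups must be present")
  sens <- 100 * mean(sl$ndpae[ae])
  spec <- 100 * mean(!sl$ndpae[!ae])
  list(sensitivity = sens, specificity = spec,
       accuracy = accuracy_from_rates(sens, spec, n_ae, n_con),
       n_ae = n_ae, n_con = n_con)
}

#' Prevalence-weighted accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity Percentages (0-100).
#' @param n_ae,n_con Group sizes.
#' @return Accuracy in percent.
#' @export
#' @examples
#' accuracy_from_rates(69.1, 77.5, 486, 679)  # 74.0
accuracy_from_rates <- function(sensitivity, specificity, n_ae, n_con) {
  (sensitivity * n_ae + specificity * n_con) / (n_ae + n_con)
}

#' Mann-Whitney AUC for an ordinal or binary predictor
#'
#' AUC as the Mann-Whitney probability that a randomly chosen positive
#' subject scores higher than a randomly chosen negative one, ties counted
#' one half. For a binary predictor this equals (TPR + TNR) / 2. The
#' standard error is Hanley-McNeil, and the p-value tests AUC = 0.5 by
#' normal approximation.
#'
#' @param scores Numeric predictor (higher = more likely positive).
#' @param labels Binary outcome (logical, or 0/1); both classes required.
#' @return A list: `auc`, `se`, `p.value`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 0))
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- if (se > 0) (auc - 0.5) / se else Inf * sign(auc - 0.5)
  list(auc = auc, se = se,
       p.value = 2 * stats::pnorm(-abs(z)), n_pos = n1, n_neg = n0)
}

#' Logistic regression of diagnosis risk on age and sex
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()], convergence tolerance 1e-8, at most 50 iterations)
#' with Wald 95% confidence intervals reported on the odds-ratio scale.
#' Sex is coded female = 1, male = 0. Complete separation or
#' non-convergence raises an error rather than returning unstable
#' estimates.
#'
#' @param formula Model formula, e.g. `ndpae ~ age + sex`.
#' @param data Data frame holding the outcome and predictors; a character
#'   or factor `sex` column is recoded to the female indicator.
#' @return A list of class `ndpae_logit`: `coefficients`, `or`
#'   (odds ratios), `ci` (2-column matrix, 95% Wald on OR scale), `p.value`,
#'   `n`, and the underlying `glm` object as `fit`.
#' @export
logistic_fit <- function(formula, data) {
  data <- as.data.frame(data)
  if ("sex" %in% names(data) && !is.numeric(data$sex)) {
    data$sex <- as.integer(as.character(data$sex) == "female")
  }
  outcome <- stats::model.response(
    stats::model.frame(formula, data = data, na.action = stats::na.omit))
  if (length(unique(as.integer(outcome))) < 2L)
    stop("outcome has a single class: model is inestimable")
  fit <- stats::glm(formula, data = data, family = stats::binomial(),
                    na.action = stats::na.omit,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 50))
  if (!fit$converged)
    stop("IRLS did not converge in ", fit$iter, " iterations")
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10 | mu > 1 - 1e-10) || any(abs(stats::coef(fit)) > 15))
    stop("separation detected after ", fit$iter,
         " IRLS iterations: coefficients diverge")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- exp(cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se))
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(coefficients = beta, or = exp(beta), ci = ci,
                 p.value = p, n = stats::nobs(fit), fit = fit),
            class = "ndpae_logit")
}

#' @export
print.ndpae_logit <- function(x, ...) {
  cat("Logistic model of diagnosis risk (n =", x$n, ")\n")
  tab <- cbind(beta = x$coefficients, OR = x$or, x$ci, p = x$p.value)
  print(round(tab, 4))
  invisible(x)
}
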