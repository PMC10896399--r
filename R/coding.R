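# Score standardization and criterion coding.
#
# All scores are mapped onto a common z-scale on which higher is better, so
# that "impaired at threshold tau" means z <= -tau for every instrument.
# Binary diagnostic flags (1 = impaired) bypass the threshold entirely.

#' Convert a raw instrument score to an oriented z-score
#'
#' Rescales a normed score to the z-scale (mean 0, SD 1) and orients it so
#' that higher values always indicate stronger functioning. Problem scales
#' (orientation `higher_worse`) are negated after rescaling. Binary
#' measures pass through unchanged (the returned value is the impairment
#' flag itself, not a z-score).
#'
#' @param raw Numeric vector of raw scores (NA allowed, propagated).
#' @param scale Scale of the measure: `"standard_100_15"`, `"t_50_10"`,
#'   `"scaled_10_3"`, `"z"`, or `"binary"`.
#' @param orientation `"higher_better"`, `"higher_worse"`, or
#'   `"binary_impaired"`.
#' @return Numeric vector: oriented z-scores, or 0/1 flags for binary
#'   measures.
#' @export
#' @examples
#' standardize_score(70, "standard_100_15", "higher_better")  # -2
#' standardize_score(70, "t_50_10", "higher_worse")           # -2
standardize_score <- function(raw, scale, orientation) {
  scale <- match.arg(scale, .scales)
  orientation <- match.arg(orientation, .orientations)
  if (any(is.infinite(raw))) stop("raw score must be finite")
  if (scale == "binary") {
    if (orientation != "binary_impaired")
      stop("binary scale requires binary_impaired orientation")
    ok <- is.na(raw) | raw %in% c(0, 1)
    if (!all(ok)) stop("binary measure value not in {0, 1}")
    return(raw)
  }
  if (orientation == "binary_impaired")
    stop("binary_impaired orientation requires binary scale")
  z <- switch(scale,
              standard_100_15 = (raw - 100) / 15,
              t_50_10         = (raw - 50) / 10,
              scaled_10_3     = (raw - 10) / 3,
              z               = raw)
  if (orientation == "higher_worse") z <- -z
  z
}

#' Code a single standardized score against an impairment threshold
#'
#' @param z Oriented z-score(s) (or 0/1 flags when `binary = TRUE`).
#' @param tau Impairment threshold in SD units (e.g. 1.0, 1.5, 2.0).
#'   Impairment is inclusive: `z <= -tau`.
#' @param binary If `TRUE`, `z` is a binary impairment flag and is returned
#'   unchanged regardless of `tau`.
#' @return Integer vector of 0/1 (NA propagated).
#' @export
code_impairment <- function(z, tau, binary = FALSE) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  if (binary) return(as.integer(z))
  as.integer(z <= -tau)
}

#' Code one criterion from its observed measures
#'
#' Implements the any-measure rule: a criterion is impaired (1) if any
#' observed measure falls in the impairment range, not impaired (0) if at
#' least one measure is observed and none are impaired, and unobserved (NA)
#' if no measure is observed.
#'
#' @param impaired Integer vector of per-measure 0/1 impairment codes (NA =
#'   measure not administered).
#' @return 1, 0, or NA.
#' @export
code_criterion <- function(impaired) {
  obs <- impaired[!is.na(impaired)]
  if (!length(obs)) return(NA_integer_)
  as.integer(any(obs == 1L))
}

#' Build the subjects x criteria ternary matrix
#'
#' Standardizes every registered score in the cohort, codes per-measure
#' impairment at threshold `tau`, and reduces measures to the 12 criteria
#' with the any-measure rule. Cells are 1 (impaired), 0 (observed, not
#' impaired) or NA (criterion unobserved).
#'
#' @param cohort An `ndpae_cohort` data frame (see [read_cohort()],
#'   [generate_cohort()]).
#' @param registry Measure registry; every score column in `cohort` must be
#'   registered.
#' @param tau Impairment threshold in SD units.
#' @param iq_tau Threshold applied to the `global_intellectual` criterion
#'   only; defaults to `tau`. Setting `iq_tau = 2` with `tau = 1` yields the
#'   hybrid model in which IQ keeps its original 2.0-SD definition.
#' @return An integer matrix (subjects x 12) of class `ndpae_cmat` with
#'   `rownames` = subject ids, `colnames` = criterion ids, and attributes
#'   `tau`, `iq_tau`, `group` (factor per subject), `cohort_n`.
#' @export
criterion_matrix <- function(cohort, registry = ndpae_registry(), tau,
                             iq_tau = tau) {
  registry <- as_registry(registry)
  stopifnot(inherits(cohort, "data.frame"))
  meas <- cohort_measures(cohort)
  extra <- setdiff(meas, registry$measure_id)
  if (length(extra))
    stop("cohort has score column(s) not in the registry: ",
         paste(extra, collapse = ", "))
  n <- nrow(cohort)
  crits <- .criteria$criterion
  m <- matrix(NA_integer_, n, length(crits),
              dimnames = list(cohort$subject_id, crits))
  for (crit in crits) {
    specs <- registry[registry$criterion == crit &
                        registry$measure_id %in% meas, , drop = FALSE]
    if (!nrow(specs)) next
    tau_c <- if (crit == "global_intellectual") iq_tau else tau
    codes <- matrix(NA_integer_, n, nrow(specs))
    for (j in seq_len(nrow(specs))) {
      z <- standardize_score(cohort[[specs$measure_id[j]]],
                             specs$scale[j], specs$orientation[j])
      codes[, j] <- code_impairment(z, tau_c,
                                    binary = specs$scale[j] == "binary")
    }
    any_obs <- rowSums(!is.na(codes)) > 0L
    any_imp <- rowSums(codes == 1L, na.rm = TRUE) > 0L
    m[, crit] <- ifelse(any_obs, as.integer(any_imp), NA_integer_)
  }
  structure(m, class = "ndpae_cmat", tau = tau, iq_tau = iq_tau,
            group = factor(cohort$group, levels = c("AE", "CON")),
            cohort_n = n)
}

#' Exclude subjects with a fully unobserved domain
#'
#' Subjects for whom every criterion of at least one domain is unobserved
#' cannot be evaluated under the diagnostic rules and are dropped, mirroring
#' the cohort-assembly exclusion for missing domain data.
#'
#' @param cmat An `ndpae_cmat` from [criterion_matrix()].
#' @return A list: `matrix` (filtered `ndpae_cmat`) and `log`, a data frame
#'   with `subject_id` and `domain` (the first domain that triggered
#'   exclusion for that subject).
#' @export
apply_exclusions <- function(cmat) {
  stopifnot(inherits(cmat, "ndpae_cmat"))
  doms <- c("NI", "SR", "AF")
  first_missing <- rep(NA_character_, nrow(cmat))
  for (d in doms) {
    cols <- .criteria$criterion[.criteria$domain == d]
    all_u <- rowSums(!is.na(cmat[, cols, drop = FALSE])) == 0L
    first_missing[is.na(first_missing) & all_u] <- d
  }
  drop <- !is.na(first_missing)
  log <- data.frame(subject_id = rownames(cmat)[drop],
                    domain = first_missing[drop],
                    stringsAsFactors = FALSE)
  kept <- cmat[!drop, , drop = FALSE]
  out <- structure(kept, class = "ndpae_cmat",
                   tau = attr(cmat, "tau"), iq_tau = attr(cmat, "iq_tau"),
                   group = attr(cmat, "group")[!drop],
                   cohort_n = attr(cmat, "cohort_n"))
  list(matrix = out, log = log)
}

#' Write a criterion matrix to CSV for audit
#'
#' One ternary column per criterion; unobserved cells are written empty.
#'
#' @param cmat An `ndpae_cmat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_criterion_matrix <- function(cmat, path) {
  df <- data.frame(subject_id = rownames(cmat),
                   as.data.frame(unclass(cmat)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
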