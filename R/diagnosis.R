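# Domain scoring and the ND-PAE diagnostic rule.
#
# Ternary criterion codes (1 impaired / 0 not / NA unobserved) are reduced
# to domain endorsements; an unobserved criterion never endorses a domain or
# a clause. A diagnosis requires NI and SR endorsement plus the adaptive-
# functioning domain under one of three models:
#   AF2of4  — (communication OR social) AND (daily_living OR motor)
#   AF1     — any of communication, social, daily_living (motor excluded)
#   hybridIQ — AF2of4 logic on the 1.0-SD matrix, with the global
#              intellectual criterion coded at its original 2.0-SD cutoff.

ternary_any <- function(...) {
  m <- cbind(...)
  rowSums(m == 1L, na.rm = TRUE) > 0L
}

#' Score the neurocognitive domain
#'
#' Endorsed iff any of the five NI criteria equals 1; unobserved criteria
#' never endorse.
#'
#' @param criteria Matrix or data frame with the five NI criterion columns
#'   (subjects x 5), or a length-5 vector for one subject. Values 0/1/NA.
#' @return Logical vector, one element per subject.
#' @export
score_ni <- function(criteria) {
  if (is.null(dim(criteria))) criteria <- matrix(criteria, nrow = 1L)
  stopifnot(ncol(criteria) == 5L)
  ternary_any(criteria)
}

#' Score the self-regulation domain
#'
#' Endorsed iff any of the three SR criteria equals 1.
#'
#' @param criteria Subjects x 3 matrix (or length-3 vector) of 0/1/NA.
#' @return Logical vector.
#' @export
score_sr <- function(criteria) {
  if (is.null(dim(criteria))) criteria <- matrix(criteria, nrow = 1L)
  stopifnot(ncol(criteria) == 3L)
  ternary_any(criteria)
}

#' Score adaptive functioning under the original 2-of-4 rule
#'
#' Endorsed iff (communication or social communication impaired) AND (daily
#' living or motor impaired).
#'
#' @param comm,social,daily,motor Vectors of 0/1/NA criterion codes.
#' @return Logical vector.
#' @export
score_af_2of4 <- function(comm, social, daily, motor) {
  ternary_any(comm, social) & ternary_any(daily, motor)
}

#' Score adaptive functioning under the modified 1-criterion rule
#'
#' Endorsed iff any of communication, social communication, or daily living
#' is impaired. Motor impairment is not a criterion under this rule.
#'
#' @param comm,social,daily Vectors of 0/1/NA criterion codes.
#' @return Logical vector.
#' @export
score_af_1 <- function(comm, social, daily) {
  ternary_any(comm, social, daily)
}

#' Combine domain endorsements into the ND-PAE classification
#'
#' @param ni,sr,af Logical vectors of domain endorsement.
#' @return Logical vector: `ni & sr & af`.
#' @export
classify_ndpae <- function(ni, sr, af) ni & sr & af

af_score <- function(cmat, model) {
  switch(model,
         AF2of4 = ,
         hybridIQ = score_af_2of4(cmat[, "communication"], cmat[, "social"],
                                  cmat[, "daily_living"], cmat[, "motor"]),
         AF1 = score_af_1(cmat[, "communication"], cmat[, "social"],
                          cmat[, "daily_living"]),
         stop("unknown model: ", model))
}

.models <- c("AF2of4", "AF1", "hybridIQ")

#' Evaluate the full threshold x model diagnosis grid
#'
#' Applies the domain rules to one criterion matrix per threshold and stacks
#' the results in long format. The `hybridIQ` model is evaluated at the
#' 1.0-SD threshold with the global-intellectual criterion recoded at 2.0 SD
#' (`hybrid_cmat`); it is skipped when `hybrid_cmat` is not supplied.
#'
#' @param cmats Named list of `ndpae_cmat` objects, names = threshold values
#'   (e.g. `list("1" = ..., "1.5" = ..., "2" = ...)`). All matrices must
#'   cover the same subjects in the same order.
#' @param models Character subset of `c("AF2of4", "AF1", "hybridIQ")`.
#' @param hybrid_cmat Criterion matrix built with `tau = 1, iq_tau = 2`
#'   (see [criterion_matrix()]); required iff `"hybridIQ"` is requested.
#' @return A data frame of class `ndpae_grid`, long format: `subject_id`,
#'   `group`, `tau`, `model`, and logical `ni`, `sr`, `af`, `ndpae`.
#' @export
diagnosis_grid <- function(cmats, models = .models, hybrid_cmat = NULL) {
  models <- match.arg(models, .models, several.ok = TRUE)
  stopifnot(length(cmats) >= 1L)
  ids <- rownames(cmats[[1L]])
  for (m in cmats) stopifnot(identical(rownames(m), ids))
  pieces <- list()
  eval_one <- function(cmat, tau_label, model) {
    ni <- score_ni(cmat[, .criteria$criterion[.criteria$domain == "NI"],
                        drop = FALSE])
    sr <- score_sr(cmat[, .criteria$criterion[.criteria$domain == "SR"],
                        drop = FALSE])
    af <- af_score(cmat, model)
    data.frame(subject_id = rownames(cmat),
               group = as.character(attr(cmat, "group")),
               tau = tau_label, model = model,
               ni = ni, sr = sr, af = af,
               ndpae = classify_ndpae(ni, sr, af),
               stringsAsFactors = FALSE)
  }
  for (model in setdiff(models, "hybridIQ")) {
    for (nm in names(cmats)) {
      pieces[[length(pieces) + 1L]] <-
        eval_one(cmats[[nm]], as.numeric(nm), model)
    }
  }
  if ("hybridIQ" %in% models) {
    if (is.null(hybrid_cmat))
      stop("hybridIQ model requested but hybrid_cmat not supplied")
    stopifnot(identical(rownames(hybrid_cmat), ids))
    pieces[[length(pieces) + 1L]] <-
      eval_one(hybrid_cmat, attr(hybrid_cmat, "tau"), "hybridIQ")
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("ndpae_grid", "data.frame")
  out
}
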