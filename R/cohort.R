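# Cohort table I/O.
#
# A cohort is a wide data frame: one row per subject, columns subject_id,
# group (AE/CON), age, sex (male/female), optional site, plus one numeric
# column per registered measure. Missing scores are NA (empty cells in CSV).

.id_cols <- c("subject_id", "group", "age", "sex", "site")

#' Read a subject-level cohort table
#'
#' Reads a CSV with one row per subject and validates it against a measure
#' registry. Required columns: `subject_id`, `group` (`AE` or `CON`), `age`
#' (years), `sex` (`male`/`female`); `site` is optional. Every remaining
#' column must name a registered measure (see `unknown` for alternatives).
#' Empty cells are missing scores.
#'
#' @param path Path to a CSV file with a header row.
#' @param registry An `ndpae_registry`, default [ndpae_registry()].
#' @param unknown What to do with score columns absent from the registry:
#'   `"error"` (default), `"warn"` (keep, with a warning), or `"drop"`.
#' @return A data frame of class `ndpae_cohort`.
#' @export
read_cohort <- function(path, registry = ndpae_registry(),
                        unknown = c("error", "warn", "drop")) {
  unknown <- match.arg(unknown)
  registry <- as_registry(registry)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  req <- setdiff(.id_cols, "site")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  score_cols <- setdiff(names(raw), .id_cols)
  extra <- setdiff(score_cols, registry$measure_id)
  if (length(extra)) {
    msg <- paste("unregistered measure column(s):",
                 paste(extra, collapse = ", "))
    if (unknown == "error") stop(msg)
    if (unknown == "warn") warning(msg)
    if (unknown == "drop") {
      raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
      score_cols <- setdiff(score_cols, extra)
    }
  }
  if (nrow(raw) == 0L) {
    out <- raw
    out[score_cols] <- lapply(out[score_cols], as.numeric)
    out$age <- numeric(0)
    class(out) <- c("ndpae_cohort", "data.frame")
    return(out)
  }
  bad_group <- !raw$group %in% c("AE", "CON")
  if (any(bad_group))
    stop("unknown group label ", sQuote(raw$group[which(bad_group)[1]]),
         " in row ", which(bad_group)[1], " (expected AE or CON)")
  num_cols <- c("age", score_cols)
  for (col in num_cols) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(parsed)
    if (any(bad))
      stop("malformed numeric value ", sQuote(v[which(bad)[1]]),
           " in row ", which(bad)[1], ", column ", sQuote(col))
    raw[[col]] <- parsed
  }
  if (anyNA(raw$age)) stop("missing age value(s)")
  as_cohort(raw)
}

as_cohort <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("subject_id", "group", "age", "sex") %in% names(x)))
  if (anyDuplicated(x$subject_id))
    stop("duplicate subject_id in cohort")
  class(x) <- unique(c("ndpae_cohort", class(x)))
  x
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: UTF-8, header row, missing scores as empty
#' cells.
#'
#' @param cohort An `ndpae_cohort` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

cohort_measures <- function(cohort) setdiff(names(cohort), .id_cols)
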