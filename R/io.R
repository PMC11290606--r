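#' Canonical column names of the long-format trial table
#'
#' @return Character vector of required columns.
#' @export
trial_columns <- function() {
  c("participant_id", "trial", "phase", "block", "role", "stimulus",
    "size_mm", "us", "k", "size_estimate_mm", "expectancy")
}

#' Validate a long-format trial table
#'
#' Enforces the schema invariants with row-level messages: required columns
#' present; roles in `CSplus`/`CSminus`/`TS`; phases in
#' `acquisition`/`generalization`; trial indices contiguous per participant;
#' `us = 0` whenever the role is not `CSplus`; expectancy within `[1, 10]`
#' when present; size estimates within `[0, 200]` when present.
#'
#' @param trials data frame.
#' @return Invisibly, `trials`; errors on violation.
#' @export
validate_trials <- function(trials) {
  miss <- setdiff(setdiff(trial_columns(), c("stimulus", "k")),
                  names(trials))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!trials$role %in% c("CSplus", "CSminus", "TS"))
  if (length(bad)) stop("invalid role at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!trials$phase %in% c("acquisition", "generalization"))
  if (length(bad)) stop("invalid phase at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(trials$us == 1 & trials$role != "CSplus")
  if (length(bad))
    stop("US delivered on a non-CS+ trial at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.na(trials$expectancy) &
                 (trials$expectancy < 1 | trials$expectancy > 10))
  # simulated ratings are untruncated; flag only hard schema use
  if (length(bad) && isTRUE(attr(trials, "strict_expectancy")))
    stop("expectancy outside [1, 10] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.na(trials$size_estimate_mm) &
                 (trials$size_estimate_mm < 0 |
                    trials$size_estimate_mm > 200))
  if (length(bad)) stop("size estimate outside [0, 200] at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  for (id in unique(trials$participant_id)) {
    tr <- sort(trials$trial[trials$participant_id == id])
    if (!identical(as.integer(tr), seq_along(tr)))
      stop("non-contiguous trial indices for participant ", id)
  }
  invisible(trials)
}

#' Read a long-format trial table from CSV
#'
#' A `dialect` maps the canonical column names to the file's column names,
#' accommodating external data layouts without guessing: e.g.
#' `dialect = c(participant_id = "subj", expectancy = "us_rating")`. When
#' reading files collected on the 1-10 expectancy VAS, `strict = TRUE`
#' rejects out-of-range ratings (synthetic ratings from the untruncated
#' response model may legitimately fall outside the scale and are read with
#' `strict = FALSE`).
#'
#' @param path CSV path.
#' @param dialect named character vector mapping canonical to file column
#'   names; unnamed entries are ignored.
#' @param strict reject expectancy values outside `[1, 10]`.
#' @return Validated trial table.
#' @export
read_trials <- function(path, dialect = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(df))
        names(df)[names(df) == dialect[[canon]]] <- canon
    }
  }
  if (!"k" %in% names(df))
    df$k <- as.integer(df$role %in% c("CSplus", "CSminus"))
  if (!"stimulus" %in% names(df)) df$stimulus <- NA_character_
  attr(df, "strict_expectancy") <- strict
  validate_trials(df)
  df[, intersect(trial_columns(), names(df))]
}

#' Write a trial table as CSV
#'
#' Nullable fields are written as empty cells.
#'
#' @param trials trial table.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}
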