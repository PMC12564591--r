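#' @keywords internal
participant_base_cols <- function() {
  c("pid", "people_told", "informed_sex_partners", "sexual_identity", "race")
}

#' @keywords internal
sexual_identity_levels <- function() c("gay_lesbian", "bisexual", "straight")

#' @keywords internal
race_levels <- function() c("black", "white", "other")

#' Validate a participant table
#'
#' A participant table has one row per respondent with columns `pid`
#' (unique character id), `people_told` (non-negative integer count of
#' people told about the respondent's HIV status), `informed_sex_partners`
#' (0/1), `sexual_identity` (`gay_lesbian`, `bisexual`, `straight`), `race`
#' (`black`, `white`, `other`) and one 0/1 column per catalog indicator,
#' already burden-coded (1 = exclusion experienced). Missing values are not
#' modeled: any `NA` is a validation error.
#'
#' @param participants a data frame of respondents.
#' @param catalog indicator catalog, see [default_catalog()].
#' @return The validated table as a tibble with columns in canonical order
#'   (base columns, then indicators in catalog order), row order preserved.
#' @export
as_participants <- function(participants, catalog = default_catalog()) {
  catalog <- validate_catalog(catalog)
  df <- tibble::as_tibble(participants)

  base <- participant_base_cols()
  miss_base <- setdiff(base, names(df))
  if (length(miss_base) > 0) {
    stop("missing required column(s): ", paste(miss_base, collapse = ", "),
         call. = FALSE)
  }
  miss_ind <- setdiff(catalog$id, names(df))
  if (length(miss_ind) > 0) {
    stop("missing indicator column(s): ", paste(miss_ind, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), c(base, catalog$id))
  if (length(extra) > 0) {
    stop("unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }

  df <- df[, c(base, catalog$id)]
  if (anyNA(df)) {
    bad <- names(df)[vapply(df, anyNA, TRUE)]
    stop("missing values are not allowed (column(s): ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }

  df$pid <- as.character(df$pid)
  if (anyDuplicated(df$pid)) stop("pid values must be unique", call. = FALSE)

  if (any(df$people_told < 0) || any(df$people_told != round(df$people_told))) {
    stop("people_told must be a non-negative integer count", call. = FALSE)
  }
  df$people_told <- as.integer(df$people_told)

  if (!all(df$informed_sex_partners %in% c(0, 1))) {
    stop("informed_sex_partners must be 0/1", call. = FALSE)
  }
  df$informed_sex_partners <- as.integer(df$informed_sex_partners)

  bad_id <- !df$sexual_identity %in% sexual_identity_levels()
  if (any(bad_id)) {
    stop("invalid sexual_identity for pid ",
         paste(df$pid[bad_id], collapse = ", "),
         " (allowed: ", paste(sexual_identity_levels(), collapse = ", "), ")",
         call. = FALSE)
  }
  bad_race <- !df$race %in% race_levels()
  if (any(bad_race)) {
    stop("invalid race for pid ", paste(df$pid[bad_race], collapse = ", "),
         " (allowed: ", paste(race_levels(), collapse = ", "), ")",
         call. = FALSE)
  }

  for (id in catalog$id) {
    bad <- !df[[id]] %in% c(0, 1)
    if (any(bad)) {
      stop("indicator '", id, "' must be 0/1; invalid value for pid ",
           paste(df$pid[bad], collapse = ", "), call. = FALSE)
    }
    df[[id]] <- as.integer(df[[id]])
  }
  df
}

#' Read a participant CSV
#'
#' Reads a participant-level survey CSV (one row per respondent; see
#' [as_participants()] for the schema) and validates it against the
#' indicator catalog. A missing or extra indicator column, a non-binary
#' indicator cell, or any empty cell is an error naming the offending
#' column or row.
#'
#' @param path path of the CSV file.
#' @param catalog indicator catalog, see [default_catalog()].
#' @return A validated participant tibble, input row order preserved.
#' @seealso [write_participants()]
#' @export
read_participants <- function(path, catalog = default_catalog()) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      pid = readr::col_character(),
      sexual_identity = readr::col_character(),
      race = readr::col_character(),
      .default = readr::col_double()
    ),
    show_col_types = FALSE
  )
  as_participants(df, catalog)
}

#' Write a participant CSV
#'
#' Writes the table in canonical column order (base columns, then the
#' indicators in catalog order). [read_participants()] round-trips the
#' output identically for all fields.
#'
#' @param participants a participant table, see [as_participants()].
#' @param path destination file path.
#' @param catalog indicator catalog, see [default_catalog()].
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path,
                               catalog = default_catalog()) {
  df <- as_participants(participants, catalog)
  readr::write_csv(df, path)
  invisible(path)
}
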