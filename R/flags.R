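#' Social Isolation Score
#'
#' The unweighted sum of the 15 binary exclusion indicators (range 0-15).
#' Indicators are stored burden-coded, so the score is simply a row sum.
#' The same quantity read as a count of distinct exclusion experiences is
#' the "cumulative burden" used by [group_mean_burden()]; the two are one
#' operation by construction, not two measures that happen to agree.
#'
#' @param participants a participant table, see [as_participants()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @return Integer vector of scores, one per row of `participants`.
#' @export
#' @examples
#' fx <- build_fixture(seed = 1)
#' table(isolation_score(fx))
isolation_score <- function(participants, catalog = default_catalog()) {
  df <- as_participants(participants, catalog)
  as.integer(rowSums(as.matrix(df[, catalog$id])))
}

#' Classify a score as socially isolated
#'
#' @param score integer vector of Social Isolation Scores in 0..15.
#' @param config threshold configuration, see [threshold_config()].
#' @return Integer 0/1 vector: 1 iff `score >= config$isolation_min`
#'   (the threshold is inclusive: "7 or higher").
#' @export
classify_isolated <- function(score, config = threshold_config()) {
  validate_threshold_config(config)
  if (any(score < 0 | score > 15)) {
    stop("scores must lie in [0, 15]", call. = FALSE)
  }
  as.integer(score >= config$isolation_min)
}

#' Derive the binary analysis flags for each respondent
#'
#' Computes, per respondent, the flags every downstream analysis is built
#' on: `told3plus` (disclosed to at least `disclosure_min` people),
#' `informed_sex_partners`, the identity flags `lgb` (gay/lesbian or
#' bisexual), `straight` and `gay_or_lesbian` (excludes bisexual), the race
#' flags `black` and `white` (never both 1; both 0 for race "other"), the
#' `isolation_score`, and `isolated` (score at or above `isolation_min`).
#'
#' `lgb` and `gay_or_lesbian` are deliberately distinct: the identity truth
#' table conditions on `lgb` while the subgroup heatmap uses
#' `gay_or_lesbian`.
#'
#' @param participants a participant table, see [as_participants()].
#' @param config threshold configuration, see [threshold_config()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @return A tibble with `pid` plus the nine derived columns, all flags
#'   integer 0/1, row order matching `participants`.
#' @export
#' @examples
#' fx <- build_fixture(seed = 1)
#' fl <- derive_flags(fx)
#' colSums(fl[, c("told3plus", "informed_sex_partners", "isolated")])
derive_flags <- function(participants, config = threshold_config(),
                         catalog = default_catalog()) {
  df <- as_participants(participants, catalog)
  validate_threshold_config(config)
  score <- isolation_score(df, catalog)
  tibble::tibble(
    pid = df$pid,
    told3plus = as.integer(df$people_told >= config$disclosure_min),
    informed_sex_partners = df$informed_sex_partners,
    lgb = as.integer(df$sexual_identity %in% c("gay_lesbian", "bisexual")),
    straight = as.integer(df$sexual_identity == "straight"),
    gay_or_lesbian = as.integer(df$sexual_identity == "gay_lesbian"),
    black = as.integer(df$race == "black"),
    white = as.integer(df$race == "white"),
    isolation_score = score,
    isolated = classify_isolated(score, config)
  )
}

# flag columns valid as truth-table conditions / heatmap groups
binary_flag_names <- function() {
  c("told3plus", "informed_sex_partners", "lgb", "straight",
    "gay_or_lesbian", "black", "white", "isolated")
}
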