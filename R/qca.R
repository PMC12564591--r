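#' Build a crisp-set QCA truth table
#'
#' Groups respondents by their configuration over a set of binary
#' conditions (derived flags, e.g. `told3plus`, `informed_sex_partners`,
#' `lgb`, `straight`) and tallies, per observed configuration, the case
#' count and the number of cases endorsing each binary outcome indicator.
#'
#' Rows are sorted ascending-lexicographically by configuration (0 before
#' 1, leftmost condition most significant), the canonical published order.
#' Configurations observed fewer than `min_freq` times are dropped from
#' `rows` (logical remainders — unobserved configurations — are never
#' listed); the unfiltered tallies are kept internally so that
#' [coverage()] remains exact.
#'
#' @param participants a participant table, see [as_participants()].
#' @param conditions character vector of 2-5 distinct derived-flag names.
#' @param outcomes character vector of catalog indicator ids to tally;
#'   defaults to the five `qca_outcome` items of the catalog.
#' @param min_freq minimum case count for a configuration to be reported
#'   (default 1, i.e. every observed configuration).
#' @param config threshold configuration, see [threshold_config()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @return An object of class `truth_table`: a list with `conditions`,
#'   `outcomes`, `rows` (tibble: one column per condition, `count`, one
#'   count column per outcome), `n_total` and `min_freq`.
#' @seealso [consistency()], [coverage()], [identify_consistent()]
#' @export
#' @examples
#' fx <- build_fixture(seed = 1)
#' build_truth_table(fx, c("told3plus", "informed_sex_partners",
#'                         "lgb", "straight"))
build_truth_table <- function(participants, conditions, outcomes = NULL,
                              min_freq = 1,
                              config = threshold_config(),
                              catalog = default_catalog()) {
  df <- as_participants(participants, catalog)
  if (length(conditions) < 2 || length(conditions) > 5) {
    stop("between 2 and 5 conditions are required", call. = FALSE)
  }
  if (anyDuplicated(conditions)) {
    stop("condition names must be distinct", call. = FALSE)
  }
  bad <- setdiff(conditions, binary_flag_names())
  if (length(bad) > 0) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  outcomes <- outcomes %||% catalog$id[as.logical(catalog$qca_outcome)]
  bad_out <- setdiff(outcomes, catalog$id)
  if (length(bad_out) > 0) {
    stop("unknown outcome(s): ", paste(bad_out, collapse = ", "),
         call. = FALSE)
  }
  if (min_freq < 1) stop("min_freq must be >= 1", call. = FALSE)

  flags <- derive_flags(df, config, catalog)
  dat <- dplyr::bind_cols(flags[, conditions], df[, outcomes])
  rows_all <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(conditions))) |>
    dplyr::summarise(count = dplyr::n(),
                     dplyr::across(dplyr::all_of(outcomes), sum),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(conditions)))
  rows_all$count <- as.integer(rows_all$count)

  structure(
    list(conditions = conditions,
         outcomes = outcomes,
         rows = rows_all[rows_all$count >= min_freq, ],
         rows_all = rows_all,
         n_total = nrow(df),
         min_freq = as.integer(min_freq),
         outcome_totals = vapply(df[, outcomes, drop = FALSE],
                                 function(x) as.integer(sum(x)), 1L)),
    class = "truth_table"
  )
}

config_key <- function(rows, conditions) {
  apply(as.matrix(rows[, conditions, drop = FALSE]), 1, paste, collapse = "")
}

match_configuration <- function(x, configuration, rows) {
  if (length(configuration) != length(x$conditions)) {
    stop("configuration must have one value per condition (",
         paste(x$conditions, collapse = ", "), ")", call. = FALSE)
  }
  key <- paste(as.integer(configuration), collapse = "")
  which(config_key(rows, x$conditions) == key)
}

#' Truth-table consistency
#'
#' Within a configuration, the proportion of cases endorsing an outcome:
#' `outcome count / case count`. This is the quantity the published truth
#' tables print as a percentage.
#'
#' @param x a `truth_table` from [build_truth_table()].
#' @param outcome one outcome id present in the table.
#' @param configuration optional 0/1 vector aligned to `x$conditions`; if
#'   omitted, consistencies for every reported row are returned, named by
#'   configuration.
#' @return A proportion in \[0, 1\], or a named vector of them.
#' @export
#' @examples
#' fx <- build_fixture(seed = 1)
#' tt <- build_truth_table(fx, c("told3plus", "informed_sex_partners",
#'                               "lgb", "straight"))
#' consistency(tt, "called_names", c(1, 1, 1, 0))  # 5/7
consistency <- function(x, outcome, configuration = NULL) {
  stopifnot(inherits(x, "truth_table"))
  if (!outcome %in% x$outcomes) {
    stop("outcome '", outcome, "' is not tallied in this table",
         call. = FALSE)
  }
  vals <- x$rows[[outcome]] / x$rows$count
  names(vals) <- config_key(x$rows, x$conditions)
  if (is.null(configuration)) return(vals)
  i <- match_configuration(x, configuration, x$rows)
  if (length(i) == 0) {
    stop("configuration not present in the truth table", call. = FALSE)
  }
  unname(vals[i])
}

#' Truth-table coverage
#'
#' Of all cases in the dataset endorsing the outcome, the proportion that
#' fall in the given configuration. The published tables print only
#' within-configuration percentages (consistency); coverage is the standard
#' csQCA complement and is provided beyond them. Computed on all observed
#' configurations regardless of `min_freq`, so coverages over the observed
#' (disjoint) configurations sum to 1.
#'
#' @param x a `truth_table` from [build_truth_table()].
#' @param configuration 0/1 vector aligned to `x$conditions`.
#' @param outcome one outcome id present in the table.
#' @return A proportion in \[0, 1\]. An outcome never observed in the data
#'   is an error (coverage undefined).
#' @export
coverage <- function(x, configuration, outcome) {
  stopifnot(inherits(x, "truth_table"))
  if (!outcome %in% x$outcomes) {
    stop("outcome '", outcome, "' is not tallied in this table",
         call. = FALSE)
  }
  total <- x$outcome_totals[[outcome]]
  if (total == 0) {
    stop("outcome '", outcome,
         "' is never observed: coverage is undefined", call. = FALSE)
  }
  i <- match_configuration(x, configuration, x$rows_all)
  if (length(i) == 0) return(0)
  x$rows_all[[outcome]][i] / total
}

#' Configurations consistently associated with an outcome
#'
#' Scans the reported truth-table rows and returns those whose consistency
#' for the outcome is at or above `threshold`, together with their case
#' counts so that small-n rows stay interpretable. No default threshold is
#' applied: it must be chosen explicitly.
#'
#' @param x a `truth_table` from [build_truth_table()].
#' @param outcome one outcome id present in the table.
#' @param threshold consistency threshold in (0, 1].
#' @return A tibble of the qualifying rows: condition columns, `count`,
#'   `outcome_count`, `consistency`.
#' @export
identify_consistent <- function(x, outcome, threshold) {
  stopifnot(inherits(x, "truth_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single proportion in (0, 1]", call. = FALSE)
  }
  cons <- unname(consistency(x, outcome))
  keep <- cons >= threshold
  out <- x$rows[keep, c(x$conditions, "count")]
  out$outcome_count <- x$rows[[outcome]][keep]
  out$consistency <- cons[keep]
  out
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Crisp-set QCA truth table (n = ", x$n_total,
      ", min_freq = ", x$min_freq, ")\n", sep = "")
  cat("Conditions:", paste(x$conditions, collapse = ", "), "\n\n")
  disp <- as.data.frame(x$rows[, c(x$conditions, "count")])
  for (o in x$outcomes) {
    disp[[o]] <- sprintf(
      "%d (%s%%)", x$rows[[o]],
      formatC(round_half_up(100 * x$rows[[o]] / x$rows$count, 1),
              format = "f", digits = 1))
  }
  print(disp, row.names = FALSE)
  invisible(x)
}
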