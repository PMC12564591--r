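#' Analysis threshold configuration
#'
#' Bundles the three cutoffs the whole pipeline depends on:
#'
#' * `disclosure_min` — minimum number of people told for a respondent to
#'   count as a high discloser (`told3plus = 1`). The default 3 encodes the
#'   "told three or more individuals" convention; thresholds are inclusive.
#' * `isolation_min` — minimum Social Isolation Score (0-15) for a
#'   respondent to count as socially isolated. Default 7; inclusive.
#' * `scatter_cap` — cap applied to the disclosure count on the scatterplot
#'   x-axis for readability. Default 10.
#'
#' @param disclosure_min integer >= 1.
#' @param isolation_min integer in 0..15.
#' @param scatter_cap integer >= 1.
#' @return An object of class `threshold_config` (a named list).
#' @export
#' @examples
#' threshold_config()
#' threshold_config(disclosure_min = 4, isolation_min = 8)  # stricter variant
threshold_config <- function(disclosure_min = 3, isolation_min = 7,
                             scatter_cap = 10) {
  cfg <- structure(
    list(disclosure_min = as.integer(disclosure_min),
         isolation_min = as.integer(isolation_min),
         scatter_cap = as.integer(scatter_cap)),
    class = "threshold_config"
  )
  validate_threshold_config(cfg)
  cfg
}

validate_threshold_config <- function(config) {
  if (!inherits(config, "threshold_config")) {
    stop("config must be created with threshold_config()", call. = FALSE)
  }
  if (is.na(config$disclosure_min) || config$disclosure_min < 1) {
    stop("disclosure_min must be an integer >= 1", call. = FALSE)
  }
  if (is.na(config$isolation_min) || config$isolation_min < 0 ||
      config$isolation_min > 15) {
    stop("isolation_min must be an integer in [0, 15]", call. = FALSE)
  }
  if (is.na(config$scatter_cap) || config$scatter_cap < 1) {
    stop("scatter_cap must be an integer >= 1", call. = FALSE)
  }
  invisible(config)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  cat("  disclosure_min:", x$disclosure_min, "(told3plus = told >= this)\n")
  cat("  isolation_min: ", x$isolation_min, "(isolated = score >= this)\n")
  cat("  scatter_cap:   ", x$scatter_cap, "\n")
  invisible(x)
}
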