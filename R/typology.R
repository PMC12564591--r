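#' Typology quadrant labels
#'
#' The four interpretive categories obtained by crossing disclosure
#' (told3plus) with isolation status:
#' higher disclosure / lower isolation ("adaptive_disclosure"),
#' higher disclosure / higher isolation ("high_exposure"),
#' lower disclosure / lower isolation ("concealed_resilient"),
#' lower disclosure / higher isolation ("hidden_vulnerability").
#'
#' @return Character vector of the four quadrant labels, canonical order.
#' @export
quadrant_levels <- function() {
  c("adaptive_disclosure", "high_exposure",
    "concealed_resilient", "hidden_vulnerability")
}

#' Assign each respondent to a typology quadrant
#'
#' The quadrant is a pure function of `(told3plus, isolated)`:
#' (1,0) adaptive_disclosure, (1,1) high_exposure,
#' (0,0) concealed_resilient, (0,1) hidden_vulnerability.
#'
#' @param flags derived-flag table from [derive_flags()].
#' @return A tibble with `pid` and `quadrant` (factor over
#'   [quadrant_levels()]).
#' @export
assign_typology <- function(flags) {
  stopifnot(all(c("pid", "told3plus", "isolated") %in% names(flags)))
  q <- ifelse(flags$told3plus == 1,
              ifelse(flags$isolated == 1, "high_exposure",
                     "adaptive_disclosure"),
              ifelse(flags$isolated == 1, "hidden_vulnerability",
                     "concealed_resilient"))
  tibble::tibble(pid = flags$pid,
                 quadrant = factor(q, levels = quadrant_levels()))
}

#' Quadrant counts and percentages
#'
#' Tallies the four-quadrant typology over a participant table. Counts
#' partition n; percentages are of the full sample, rounded to one decimal
#' (half away from zero).
#'
#' @param participants a participant table, see [as_participants()].
#' @param config threshold configuration, see [threshold_config()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @return A tibble with one row per quadrant: `quadrant`, `count`,
#'   `percent`. Empty input is an error (percentages undefined).
#' @export
#' @examples
#' typology_table(build_fixture(seed = 1))
typology_table <- function(participants, config = threshold_config(),
                           catalog = default_catalog()) {
  df <- as_participants(participants, catalog)
  n <- nrow(df)
  if (n < 1) stop("empty input: quadrant percentages are undefined",
                  call. = FALSE)
  assign <- assign_typology(derive_flags(df, config, catalog))
  counts <- as.integer(table(assign$quadrant))
  tibble::tibble(
    quadrant = factor(quadrant_levels(), levels = quadrant_levels()),
    count = counts,
    percent = round_half_up(100 * counts / n, 1)
  )
}
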