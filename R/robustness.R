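#' Threshold robustness check
#'
#' Re-runs the typology and the csQCA truth tables under an alternate
#' (normally stricter) threshold configuration and reports stability: both
#' typology tables, the list of respondents whose quadrant changed, both
#' truth tables per condition set, and the per-configuration consistency
#' deltas for configurations observed under both configurations.
#'
#' Raising thresholds is monotone: a respondent can only move from high to
#' low disclosure and from isolated to not-isolated, never the reverse.
#' This is asserted internally when `alternate` is stricter.
#'
#' @param participants a participant table, see [as_participants()].
#' @param baseline baseline [threshold_config()] (default 3 / 7).
#' @param alternate alternate [threshold_config()] (default 4 / 8, the
#'   stricter variant used for the published robustness summary).
#' @param condition_sets named list of condition vectors for
#'   [build_truth_table()]; defaults to the identity and race models.
#' @param outcomes outcome ids passed to [build_truth_table()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @param allow_looser set TRUE to permit an alternate configuration that
#'   is not uniformly stricter than the baseline.
#' @return An object of class `robustness_report`: a list with `baseline`,
#'   `alternate`, `typology` (tables under each config), `assignments`,
#'   `movements` (tibble `pid`, `from`, `to`), `truth_tables`, and
#'   `consistency_deltas`.
#' @export
#' @examples
#' rob <- run_robustness(build_fixture(seed = 1))
#' rob$typology$alternate
run_robustness <- function(participants,
                           baseline = threshold_config(),
                           alternate = threshold_config(disclosure_min = 4,
                                                        isolation_min = 8),
                           condition_sets = list(
                             identity = c("told3plus", "informed_sex_partners",
                                          "lgb", "straight"),
                             race = c("told3plus", "informed_sex_partners",
                                      "black", "white")),
                           outcomes = NULL,
                           catalog = default_catalog(),
                           allow_looser = FALSE) {
  df <- as_participants(participants, catalog)
  validate_threshold_config(baseline)
  validate_threshold_config(alternate)
  stricter <- alternate$disclosure_min >= baseline$disclosure_min &&
    alternate$isolation_min >= baseline$isolation_min
  if (!stricter && !allow_looser) {
    stop("alternate thresholds must be at least as strict as the baseline ",
         "(or set allow_looser = TRUE)", call. = FALSE)
  }

  fl_b <- derive_flags(df, baseline, catalog)
  fl_a <- derive_flags(df, alternate, catalog)
  as_b <- assign_typology(fl_b)
  as_a <- assign_typology(fl_a)

  if (stricter) {
    # monotone threshold response
    stopifnot(all(fl_a$told3plus <= fl_b$told3plus),
              all(fl_a$isolated <= fl_b$isolated))
  }

  moved <- as.character(as_b$quadrant) != as.character(as_a$quadrant)
  movements <- tibble::tibble(
    pid = df$pid[moved],
    from = as.character(as_b$quadrant)[moved],
    to = as.character(as_a$quadrant)[moved]
  )

  tts <- lapply(condition_sets, function(conds) {
    list(
      baseline = build_truth_table(df, conds, outcomes = outcomes,
                                   config = baseline, catalog = catalog),
      alternate = build_truth_table(df, conds, outcomes = outcomes,
                                    config = alternate, catalog = catalog)
    )
  })

  deltas <- lapply(names(tts), function(nm) {
    tb <- tts[[nm]]$baseline
    ta <- tts[[nm]]$alternate
    kb <- config_key(tb$rows, tb$conditions)
    ka <- config_key(ta$rows, ta$conditions)
    shared <- intersect(kb, ka)
    if (length(shared) == 0) return(NULL)
    out <- list()
    for (o in tb$outcomes) {
      cb <- consistency(tb, o)[shared]
      ca <- consistency(ta, o)[shared]
      out[[o]] <- tibble::tibble(
        model = nm, configuration = shared, outcome = o,
        consistency_baseline = unname(cb),
        consistency_alternate = unname(ca),
        delta = unname(ca - cb)
      )
    }
    dplyr::bind_rows(out)
  })

  structure(
    list(
      baseline = baseline,
      alternate = alternate,
      typology = list(
        baseline = typology_table(df, baseline, catalog),
        alternate = typology_table(df, alternate, catalog)
      ),
      assignments = list(baseline = as_b, alternate = as_a),
      movements = movements,
      truth_tables = tts,
      consistency_deltas = dplyr::bind_rows(deltas)
    ),
    class = "robustness_report"
  )
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Threshold robustness report\n")
  cat(sprintf("  baseline:  disclosure >= %d, isolation >= %d\n",
              x$baseline$disclosure_min, x$baseline$isolation_min))
  cat(sprintf("  alternate: disclosure >= %d, isolation >= %d\n",
              x$alternate$disclosure_min, x$alternate$isolation_min))
  cat("\nTypology counts (baseline -> alternate):\n")
  tb <- x$typology$baseline
  ta <- x$typology$alternate
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-22s %2d -> %2d\n", as.character(tb$quadrant[i]),
                tb$count[i], ta$count[i]))
  }
  cat("\n", nrow(x$movements), " respondent(s) changed quadrant\n", sep = "")
  invisible(x)
}
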