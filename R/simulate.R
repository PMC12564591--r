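#' Parameters for the synthetic survey generator
#'
#' Describes the sampling distribution [generate_random()] draws from. The
#' defaults emulate the composition of the pilot sample the analysis was
#' designed around: 17 respondents; disclosure counts with mass 7/17 spread
#' over 0-2 and 10/17 over 3-10; partner disclosure with probability 0.9
#' given broad disclosure and 0 otherwise (no low-disclosure respondent
#' informed partners); identity probabilities 11/17, 2/17, 4/17 for
#' gay/lesbian, bisexual, straight; race probabilities 13/17, 3/17, 1/17
#' for Black, White, other; and indicator prevalences of 0.58 for broad
#' disclosers and 0.44 otherwise, mirroring the observed group burden
#' rates (84/135 and 46/105).
#'
#' @param n number of respondents (>= 0).
#' @param told_support integer support of the disclosure-count
#'   distribution.
#' @param told_probs probabilities over `told_support` (must sum to 1).
#' @param p_informed_high,p_informed_low probability of partner disclosure
#'   given `people_told >= disclosure_min` / below it.
#' @param identity_probs named probabilities over
#'   `gay_lesbian, bisexual, straight` (sum to 1).
#' @param race_probs named probabilities over `black, white, other`
#'   (sum to 1).
#' @param indicator_prevalence per-indicator Bernoulli prevalence used when
#'   `condition_flag` is `NULL`: a scalar or a named vector over catalog
#'   ids.
#' @param condition_flag optional flag name (`"told3plus"` by default)
#'   conditioning indicator prevalence on a subgroup; set `NULL` for a
#'   single unconditional prevalence.
#' @param prevalence_when_1,prevalence_when_0 prevalences (scalar or named
#'   vector) used when `condition_flag` is 1 / 0.
#' @param disclosure_min threshold defining the conditioning flag.
#' @param seed integer seed; identical parameters and seed give identical
#'   datasets.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(n = 17,
                             told_support = 0:10,
                             told_probs = c(rep((7 / 17) / 3, 3),
                                            rep((10 / 17) / 8, 8)),
                             p_informed_high = 0.9,
                             p_informed_low = 0,
                             identity_probs = c(gay_lesbian = 11 / 17,
                                                bisexual = 2 / 17,
                                                straight = 4 / 17),
                             race_probs = c(black = 13 / 17,
                                            white = 3 / 17,
                                            other = 1 / 17),
                             indicator_prevalence = 0.5,
                             condition_flag = "told3plus",
                             prevalence_when_1 = 0.58,
                             prevalence_when_0 = 0.44,
                             disclosure_min = 3,
                             seed = 1L) {
  p <- structure(
    list(n = as.integer(n), told_support = as.integer(told_support),
         told_probs = told_probs, p_informed_high = p_informed_high,
         p_informed_low = p_informed_low, identity_probs = identity_probs,
         race_probs = race_probs,
         indicator_prevalence = indicator_prevalence,
         condition_flag = condition_flag,
         prevalence_when_1 = prevalence_when_1,
         prevalence_when_0 = prevalence_when_0,
         disclosure_min = as.integer(disclosure_min),
         seed = as.integer(seed)),
    class = "synthetic_params"
  )
  validate_synthetic_params(p)
  p
}

validate_synthetic_params <- function(p) {
  stopifnot(inherits(p, "synthetic_params"))
  if (is.na(p$n) || p$n < 0) stop("n must be >= 0", call. = FALSE)
  chk_probs <- function(x, nm) {
    if (any(x < 0 | x > 1)) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  chk_sum1 <- function(x, nm) {
    chk_probs(x, nm)
    if (abs(sum(x) - 1) > 1e-8) {
      stop(nm, " must sum to 1", call. = FALSE)
    }
  }
  if (length(p$told_probs) != length(p$told_support)) {
    stop("told_probs must match told_support in length", call. = FALSE)
  }
  chk_sum1(p$told_probs, "told_probs")
  chk_sum1(p$identity_probs, "identity_probs")
  chk_sum1(p$race_probs, "race_probs")
  chk_probs(c(p$p_informed_high, p$p_informed_low), "partner probabilities")
  chk_probs(p$indicator_prevalence, "indicator_prevalence")
  if (!is.null(p$condition_flag)) {
    chk_probs(p$prevalence_when_1, "prevalence_when_1")
    chk_probs(p$prevalence_when_0, "prevalence_when_0")
  }
  if (!setequal(names(p$identity_probs), sexual_identity_levels())) {
    stop("identity_probs must be named over: ",
         paste(sexual_identity_levels(), collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(p$race_probs), race_levels())) {
    stop("race_probs must be named over: ",
         paste(race_levels(), collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

expand_prevalence <- function(prev, catalog) {
  if (length(prev) == 1 && is.null(names(prev))) {
    return(stats::setNames(rep(prev, nrow(catalog)), catalog$id))
  }
  missing <- setdiff(catalog$id, names(prev))
  if (length(missing) > 0) {
    stop("prevalence vector is missing indicator(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prev[catalog$id]
}

#' Generate a random synthetic survey
#'
#' Draws `params$n` independent respondents from the distributions in
#' `params`: a disclosure count, partner disclosure conditional on breadth
#' of disclosure, identity and race categories, and independent Bernoulli
#' exclusion indicators whose prevalence may be conditioned on a subgroup
#' flag. Reproducible given the seed.
#'
#' @param params a [synthetic_params()] object.
#' @param catalog indicator catalog, see [default_catalog()].
#' @param seed optional override of `params$seed`.
#' @return A validated participant tibble with `params$n` rows.
#' @export
#' @examples
#' synth <- generate_random(synthetic_params(n = 5, seed = 7))
#' nrow(synth)
generate_random <- function(params = synthetic_params(),
                            catalog = default_catalog(),
                            seed = NULL) {
  validate_synthetic_params(params)
  catalog <- validate_catalog(catalog)
  n <- params$n
  empty <- tibble::tibble(
    pid = character(), people_told = integer(),
    informed_sex_partners = integer(), sexual_identity = character(),
    race = character()
  )
  for (id in catalog$id) empty[[id]] <- integer()
  if (n == 0) return(empty)

  withr::with_seed(as.integer(seed %||% params$seed), {
    told <- sample(params$told_support, n, replace = TRUE,
                   prob = params$told_probs)
    high <- told >= params$disclosure_min
    informed <- stats::rbinom(
      n, 1, ifelse(high, params$p_informed_high, params$p_informed_low))
    identity <- sample(names(params$identity_probs), n, replace = TRUE,
                       prob = params$identity_probs)
    race <- sample(names(params$race_probs), n, replace = TRUE,
                   prob = params$race_probs)

    if (is.null(params$condition_flag)) {
      prev1 <- prev0 <- expand_prevalence(params$indicator_prevalence,
                                          catalog)
      cond <- rep(FALSE, n)
    } else {
      prev1 <- expand_prevalence(params$prevalence_when_1, catalog)
      prev0 <- expand_prevalence(params$prevalence_when_0, catalog)
      cond <- switch(
        params$condition_flag,
        told3plus = high,
        informed_sex_partners = informed == 1,
        lgb = identity %in% c("gay_lesbian", "bisexual"),
        straight = identity == "straight",
        gay_or_lesbian = identity == "gay_lesbian",
        black = race == "black",
        white = race == "white",
        stop("unsupported condition_flag: ", params$condition_flag,
             call. = FALSE)
      )
    }

    out <- tibble::tibble(
      pid = sprintf("S%04d", seq_len(n)),
      people_told = as.integer(told),
      informed_sex_partners = as.integer(informed),
      sexual_identity = identity,
      race = race
    )
    for (id in catalog$id) {
      p <- ifelse(cond, prev1[[id]], prev0[[id]])
      out[[id]] <- stats::rbinom(n, 1, p)
    }
    as_participants(out, catalog)
  })
}
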