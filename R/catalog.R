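#' The seven social-exclusion domains
#'
#' @return Character vector of the seven domain labels used by the
#'   indicator catalog and the domain burden profiles.
#' @export
domain_labels <- function() {
  c("Family", "Community", "Social Support", "Healthcare",
    "Housing", "Workplace", "LGBT Community")
}

#' Default 15-item social-exclusion indicator catalog
#'
#' The Social Isolation Index is the unweighted sum of 15 binary indicators
#' of exclusion spanning seven domains of social life. The underlying survey
#' instrument is not published in full, so this catalog is a documented
#' stand-in: it contains every item the source study names (having no one to
#' turn to, friends growing distant after disclosure, feeling part of the
#' LGBT community, unfair treatment at work, the five csQCA outcome items)
#' and fills the remaining slots with plausible items so that all seven
#' domains are populated. Users with access to the real instrument can
#' substitute their own catalog via [read_catalog()].
#'
#' All indicators are stored burden-coded (1 = exclusion experienced).
#' `reverse_coded = TRUE` marks items whose raw survey wording is positive
#' ("I feel part of the LGBT community") and must be flipped at ingestion;
#' that conversion is the caller's responsibility.
#'
#' Exactly five items are flagged `qca_outcome`: family rejection, friend
#' rejection, being called names, unfair treatment at work, and moving
#' because of stigma. These are the outcomes tallied in the truth tables.
#'
#' @return A tibble with columns `id`, `text`, `domain`, `reverse_coded`,
#'   `qca_outcome`; one row per indicator, in canonical order.
#' @seealso [validate_catalog()], [read_catalog()], [write_catalog()]
#' @export
#' @examples
#' default_catalog()
default_catalog <- function() {
  tibble::tribble(
    ~id,                 ~text,                                                          ~domain,          ~reverse_coded, ~qca_outcome,
    "family_rejects",    "Family members rejected me after learning my HIV status",     "Family",         FALSE, TRUE,
    "family_distant",    "Family members have become distant since my diagnosis",       "Family",         FALSE, FALSE,
    "called_names",      "I have been called names because of my HIV status",           "Community",      FALSE, TRUE,
    "moved_stigma",      "I have moved because of stigma in my community",               "Community",      FALSE, TRUE,
    "community_excluded","I feel excluded from activities in my community",             "Community",      FALSE, FALSE,
    "no_one_to_turn_to", "I feel like I have no one to turn to",                         "Social Support", FALSE, FALSE,
    "friends_reject",    "Friends rejected me after learning my HIV status",             "Social Support", FALSE, TRUE,
    "friends_distant",   "Friends are distant after revealing my HIV status",            "Social Support", FALSE, FALSE,
    "partner_rejects",   "A partner rejected me because of my HIV status",               "Social Support", FALSE, FALSE,
    "unfair_healthcare", "I am treated unfairly when seeking healthcare",                "Healthcare",     FALSE, FALSE,
    "housing_trouble",   "I have had trouble finding or keeping housing",                "Housing",        FALSE, FALSE,
    "work_unfair",       "I am treated unfairly at work",                                "Workplace",      FALSE, TRUE,
    "work_excluded",     "I am excluded by coworkers at my workplace",                   "Workplace",      FALSE, FALSE,
    "not_part_lgbt",     "I feel part of the LGBT community",                            "LGBT Community", TRUE,  FALSE,
    "lgbt_excluded",     "I feel excluded from LGBT community spaces",                   "LGBT Community", FALSE, FALSE
  )
}

# the five outcome ids every valid catalog must flag
qca_outcome_ids <- function() {
  c("family_rejects", "friends_reject", "called_names", "work_unfair",
    "moved_stigma")
}

#' Validate an indicator catalog
#'
#' Checks the structural invariants every catalog must satisfy: exactly 15
#' items with unique ids; every domain label drawn from [domain_labels()] and
#' every domain represented by at least one item; exactly the five csQCA
#' outcome items flagged `qca_outcome`.
#'
#' @param catalog a catalog data frame as returned by [default_catalog()].
#' @return The catalog, invisibly, as a tibble. Errors on any violation.
#' @export
validate_catalog <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  need <- c("id", "text", "domain", "reverse_coded", "qca_outcome")
  missing <- setdiff(need, names(catalog))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(catalog) != 15) {
    stop("catalog must contain exactly 15 items, got ", nrow(catalog),
         call. = FALSE)
  }
  if (anyDuplicated(catalog$id)) {
    stop("catalog ids must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(catalog$domain), domain_labels())
  if (length(bad) > 0) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(domain_labels(), catalog$domain)
  if (length(absent) > 0) {
    stop("every domain needs at least one item; missing: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  flagged <- catalog$id[as.logical(catalog$qca_outcome)]
  if (!setequal(flagged, qca_outcome_ids()) || length(flagged) != 5) {
    stop("exactly the five outcome items (",
         paste(qca_outcome_ids(), collapse = ", "),
         ") must be flagged qca_outcome", call. = FALSE)
  }
  invisible(catalog)
}

#' Read / write an indicator catalog as YAML
#'
#' The catalog is serialized as a YAML list of items so that users can
#' substitute the true survey instrument for the shipped stand-in.
#'
#' @param path file path of the YAML catalog.
#' @return `read_catalog()` returns a validated catalog tibble;
#'   `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- raw$items %||% raw
  catalog <- tibble::tibble(
    id = vapply(items, function(x) as.character(x$id), ""),
    text = vapply(items, function(x) as.character(x$text), ""),
    domain = vapply(items, function(x) as.character(x$domain), ""),
    reverse_coded = vapply(items, function(x) isTRUE(x$reverse_coded), TRUE),
    qca_outcome = vapply(items, function(x) isTRUE(x$qca_outcome), TRUE)
  )
  validate_catalog(catalog)
  catalog
}

#' @rdname read_catalog
#' @param catalog a catalog data frame, see [default_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  catalog <- validate_catalog(catalog)
  items <- lapply(seq_len(nrow(catalog)), function(i) {
    list(id = catalog$id[i], text = catalog$text[i],
         domain = catalog$domain[i],
         reverse_coded = catalog$reverse_coded[i],
         qca_outcome = catalog$qca_outcome[i])
  })
  yaml::write_yaml(list(items = items), path)
  invisible(path)
}
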