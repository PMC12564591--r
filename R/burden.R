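#' Disclosure group labels
#'
#' The four groups obtained by crossing breadth of disclosure (told3plus)
#' with partner disclosure: high_partner (1,1), high_nopartner (1,0),
#' low_partner (0,1), low_nopartner (0,0).
#'
#' @return Character vector of the four labels, canonical order.
#' @export
disclosure_group_levels <- function() {
  c("high_partner", "high_nopartner", "low_partner", "low_nopartner")
}

#' Map derived flags to a disclosure group
#'
#' @param flags derived-flag table from [derive_flags()].
#' @return Factor over [disclosure_group_levels()], one value per row.
#' @export
disclosure_group <- function(flags) {
  stopifnot(all(c("told3plus", "informed_sex_partners") %in% names(flags)))
  g <- ifelse(flags$told3plus == 1,
              ifelse(flags$informed_sex_partners == 1,
                     "high_partner", "high_nopartner"),
              ifelse(flags$informed_sex_partners == 1,
                     "low_partner", "low_nopartner"))
  factor(g, levels = disclosure_group_levels())
}

#' Mean cumulative burden by disclosure group
#'
#' The cumulative burden score is the 15-indicator sum (identical to the
#' Social Isolation Score, see [isolation_score()]). This tallies, for each
#' disclosure group, the group size, the total burden, and the unrounded
#' group mean. Empty groups are reported with `n = 0` and `mean = NA`.
#' Round the mean with [round_half_up()] (one decimal) to match the
#' published presentation.
#'
#' @param participants a participant table, see [as_participants()].
#' @param config threshold configuration, see [threshold_config()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @return A tibble with one row per disclosure group: `group`, `n`,
#'   `total_burden`, `mean_burden` (unrounded; NA when `n` is 0).
#' @export
#' @examples
#' gm <- group_mean_burden(build_fixture(seed = 1))
#' transform(gm, mean_1dp = round_half_up(mean_burden, 1))
group_mean_burden <- function(participants, config = threshold_config(),
                              catalog = default_catalog()) {
  df <- as_participants(participants, catalog)
  if (nrow(df) < 1) stop("empty input", call. = FALSE)
  flags <- derive_flags(df, config, catalog)
  grp <- disclosure_group(flags)
  score <- flags$isolation_score
  n <- as.integer(table(grp))
  total <- as.integer(tapply(score, grp, sum, default = 0L))
  tibble::tibble(
    group = factor(disclosure_group_levels(),
                   levels = disclosure_group_levels()),
    n = n,
    total_burden = total,
    mean_burden = ifelse(n > 0, total / n, NA_real_)
  )
}

#' Domain-specific burden profile of a disclosure group
#'
#' Disaggregates the 15 indicators into the seven thematic domains and, for
#' one disclosure group, computes each domain's burden score: the mean over
#' group members of the member's within-domain indicator mean. Values lie
#' in \[0, 1\] and are invariant to indicator order. These are the values a
#' radar chart of multidimensional burden displays.
#'
#' Note the assignment of the ten non-outcome indicators to domains follows
#' the stand-in catalog, so domain profiles have no published ground truth.
#'
#' @param participants a participant table, see [as_participants()].
#' @param group one of [disclosure_group_levels()].
#' @param config threshold configuration, see [threshold_config()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @return A tibble with one row per domain: `group`, `n`, `domain`,
#'   `value`. An empty group is an error.
#' @export
domain_profile <- function(participants, group,
                           config = threshold_config(),
                           catalog = default_catalog()) {
  group <- match.arg(group, disclosure_group_levels())
  df <- as_participants(participants, catalog)
  flags <- derive_flags(df, config, catalog)
  members <- df[as.character(disclosure_group(flags)) == group, ]
  if (nrow(members) == 0) {
    stop("disclosure group '", group, "' is empty", call. = FALSE)
  }
  vals <- vapply(domain_labels(), function(d) {
    items <- catalog$id[catalog$domain == d]
    per_member <- rowMeans(as.matrix(members[, items, drop = FALSE]))
    mean(per_member)
  }, 0)
  tibble::tibble(
    group = group,
    n = nrow(members),
    domain = factor(domain_labels(), levels = domain_labels()),
    value = unname(vals)
  )
}

#' Indicator counts and percentages by subgroup (heatmap data)
#'
#' For each subgroup defined by a derived binary flag (membership =
#' flag == 1), tallies how many members report each of the 15 indicators.
#' This is the data behind the group-by-indicator heatmap. Percentages are
#' stored unrounded; the published cells use whole-percent rounding, i.e.
#' `round_half_up(percent, 0)`.
#'
#' @param participants a participant table, see [as_participants()].
#' @param config threshold configuration, see [threshold_config()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @param groups character vector of derived-flag names defining the
#'   subgroups; defaults to the six published categories.
#' @return A long tibble with columns `group`, `n`, `indicator`, `count`,
#'   `percent` (NA with `n = 0` for an empty subgroup).
#' @export
#' @examples
#' hm <- indicator_heatmap(build_fixture(seed = 1))
#' subset(hm, indicator == "called_names")
indicator_heatmap <- function(participants, config = threshold_config(),
                              catalog = default_catalog(),
                              groups = c("told3plus", "informed_sex_partners",
                                         "gay_or_lesbian", "straight",
                                         "black", "white")) {
  df <- as_participants(participants, catalog)
  bad <- setdiff(groups, binary_flag_names())
  if (length(bad) > 0) {
    stop("unknown group flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  flags <- derive_flags(df, config, catalog)
  out <- lapply(groups, function(g) {
    members <- df[flags[[g]] == 1, ]
    n <- nrow(members)
    counts <- if (n > 0) {
      as.integer(colSums(as.matrix(members[, catalog$id])))
    } else {
      rep(0L, nrow(catalog))
    }
    pct <- if (n > 0) 100 * counts / n else rep(NA_real_, length(counts))
    tibble::tibble(group = g, n = n, indicator = catalog$id,
                   count = counts, percent = pct)
  })
  res <- dplyr::bind_rows(out)
  res$group <- factor(res$group, levels = groups)
  res$indicator <- factor(res$indicator, levels = catalog$id)
  res
}

#' Scatterplot data: disclosure count vs. isolation score
#'
#' Prepares the data behind the disclosure-versus-isolation scatterplot:
#' the disclosure count capped at `config$scatter_cap` on the x-axis, the
#' Social Isolation Score on the y-axis, and seeded uniform jitter of
#' +/- 0.15 on both axes to reduce point overlap. Reference lines are the
#' sample median of the capped disclosure count and the isolation
#' threshold. The median is computed on the capped (plotted) values; use
#' `x_raw` to recompute it uncapped if preferred.
#'
#' @param participants a participant table, see [as_participants()].
#' @param config threshold configuration, see [threshold_config()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @param jitter_seed integer seed for the jitter; identical seeds give
#'   identical output.
#' @return A list with `points` (tibble: `pid`, `x_raw`, `x_capped`, `y`,
#'   `x_jit`, `y_jit`), `x_median` and `y_threshold`.
#' @export
prepare_scatter <- function(participants, config = threshold_config(),
                            catalog = default_catalog(), jitter_seed = 1L) {
  df <- as_participants(participants, catalog)
  if (nrow(df) < 1) stop("empty input", call. = FALSE)
  validate_threshold_config(config)
  score <- isolation_score(df, catalog)
  x_capped <- pmin(df$people_told, config$scatter_cap)
  jit <- withr::with_seed(as.integer(jitter_seed), {
    list(x = stats::runif(nrow(df), -0.15, 0.15),
         y = stats::runif(nrow(df), -0.15, 0.15))
  })
  list(
    points = tibble::tibble(
      pid = df$pid,
      x_raw = df$people_told,
      x_capped = as.integer(x_capped),
      y = score,
      x_jit = x_capped + jit$x,
      y_jit = score + jit$y
    ),
    x_median = stats::median(x_capped),
    y_threshold = config$isolation_min
  )
}
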