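# Brute-force oracles: every quantity recomputed with plain loops straight
# from the raw participant columns, independent of the package's grouping
# and tallying code paths.

indicator_ids <- default_catalog()$id

oracle_score <- function(df, i) {
  s <- 0L
  for (id in indicator_ids) s <- s + df[[id]][i]
  s
}

oracle_flag <- function(df, i, flag, dmin = 3, imin = 7) {
  switch(flag,
    told3plus = as.integer(df$people_told[i] >= dmin),
    informed_sex_partners = df$informed_sex_partners[i],
    lgb = as.integer(df$sexual_identity[i] %in% c("gay_lesbian", "bisexual")),
    straight = as.integer(df$sexual_identity[i] == "straight"),
    gay_or_lesbian = as.integer(df$sexual_identity[i] == "gay_lesbian"),
    black = as.integer(df$race[i] == "black"),
    white = as.integer(df$race[i] == "white"),
    isolated = as.integer(oracle_score(df, i) >= imin),
    stop("unknown flag ", flag)
  )
}

oracle_typology_counts <- function(df, dmin = 3, imin = 7) {
  counts <- c(adaptive_disclosure = 0L, high_exposure = 0L,
              concealed_resilient = 0L, hidden_vulnerability = 0L)
  for (i in seq_len(nrow(df))) {
    t3 <- oracle_flag(df, i, "told3plus", dmin)
    iso <- oracle_flag(df, i, "isolated", imin = imin)
    q <- if (t3 == 1 && iso == 0) "adaptive_disclosure"
         else if (t3 == 1) "high_exposure"
         else if (iso == 0) "concealed_resilient"
         else "hidden_vulnerability"
    counts[q] <- counts[q] + 1L
  }
  counts
}

oracle_group_means <- function(df, dmin = 3) {
  tot <- c(high_partner = 0, high_nopartner = 0, low_partner = 0,
           low_nopartner = 0)
  n <- c(high_partner = 0L, high_nopartner = 0L, low_partner = 0L,
         low_nopartner = 0L)
  for (i in seq_len(nrow(df))) {
    t3 <- oracle_flag(df, i, "told3plus", dmin)
    inf <- df$informed_sex_partners[i]
    g <- if (t3 == 1 && inf == 1) "high_partner"
         else if (t3 == 1) "high_nopartner"
         else if (inf == 1) "low_partner"
         else "low_nopartner"
    tot[g] <- tot[g] + oracle_score(df, i)
    n[g] <- n[g] + 1L
  }
  list(n = n, total = tot, mean = ifelse(n > 0, tot / n, NA_real_))
}

oracle_heatmap_cell <- function(df, flag, indicator, dmin = 3, imin = 7) {
  cnt <- 0L
  n <- 0L
  for (i in seq_len(nrow(df))) {
    if (oracle_flag(df, i, flag, dmin, imin) == 1) {
      n <- n + 1L
      cnt <- cnt + df[[indicator]][i]
    }
  }
  list(count = cnt, n = n)
}

oracle_domain_value <- function(df, group, domain, dmin = 3) {
  catalog <- default_catalog()
  items <- catalog$id[catalog$domain == domain]
  vals <- c()
  for (i in seq_len(nrow(df))) {
    t3 <- oracle_flag(df, i, "told3plus", dmin)
    inf <- df$informed_sex_partners[i]
    g <- if (t3 == 1 && inf == 1) "high_partner"
         else if (t3 == 1) "high_nopartner"
         else if (inf == 1) "low_partner"
         else "low_nopartner"
    if (g != group) next
    member_sum <- 0
    for (id in items) member_sum <- member_sum + df[[id]][i]
    vals <- c(vals, member_sum / length(items))
  }
  mean(vals)
}

oracle_config_of <- function(df, i, conditions, dmin = 3, imin = 7) {
  paste(vapply(conditions,
               function(cn) oracle_flag(df, i, cn, dmin, imin), 1L),
        collapse = "")
}

# per observed configuration: case count and outcome tallies
oracle_truth_table <- function(df, conditions, outcomes, dmin = 3,
                               imin = 7) {
  res <- list()
  for (i in seq_len(nrow(df))) {
    key <- oracle_config_of(df, i, conditions, dmin, imin)
    if (is.null(res[[key]])) {
      res[[key]] <- c(count = 0L, setNames(rep(0L, length(outcomes)),
                                           outcomes))
    }
    res[[key]]["count"] <- res[[key]]["count"] + 1L
    for (o in outcomes) res[[key]][o] <- res[[key]][o] + df[[o]][i]
  }
  res
}

oracle_consistency <- function(df, conditions, cfg, outcome, dmin = 3,
                               imin = 7) {
  key <- paste(cfg, collapse = "")
  n <- 0L
  k <- 0L
  for (i in seq_len(nrow(df))) {
    if (oracle_config_of(df, i, conditions, dmin, imin) == key) {
      n <- n + 1L
      k <- k + df[[outcome]][i]
    }
  }
  k / n
}

oracle_coverage <- function(df, conditions, cfg, outcome, dmin = 3,
                            imin = 7) {
  key <- paste(cfg, collapse = "")
  both <- 0L
  tot <- 0L
  for (i in seq_len(nrow(df))) {
    if (df[[outcome]][i] == 1) {
      tot <- tot + 1L
      if (oracle_config_of(df, i, conditions, dmin, imin) == key) {
        both <- both + 1L
      }
    }
  }
  both / tot
}

# random dataset populating all four disclosure groups
rand_participants <- function(n, seed) {
  generate_random(
    synthetic_params(n = n, p_informed_high = 0.7, p_informed_low = 0.3,
                     seed = seed)
  )
}
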