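identity_conditions <- c("told3plus", "informed_sex_partners", "lgb",
                         "straight")
race_conditions <- c("told3plus", "informed_sex_partners", "black", "white")

test_that("truth tables on the fixture reproduce both published tables", {
  fx <- cached_fixture()
  outs <- c("family_rejects", "friends_reject", "called_names",
            "work_unfair", "moved_stigma")

  tt <- build_truth_table(fx, identity_conditions)
  expect_equal(tt$rows$count, c(1L, 6L, 1L, 2L, 7L))
  expected_identity <- list(
    family_rejects = c(0, 3, 0, 2, 3), friends_reject = c(0, 3, 0, 2, 3),
    called_names = c(0, 4, 0, 2, 5), work_unfair = c(0, 1, 0, 2, 4),
    moved_stigma = c(0, 3, 0, 1, 3))
  for (o in outs) expect_equal(tt$rows[[o]], expected_identity[[o]])

  tr <- build_truth_table(fx, race_conditions)
  expect_equal(tr$rows$count, c(1L, 6L, 1L, 1L, 2L, 6L))
  expected_race <- list(
    family_rejects = c(0, 3, 0, 0, 1, 4), friends_reject = c(1, 2, 0, 0, 1, 4),
    called_names = c(1, 3, 0, 0, 2, 5), work_unfair = c(0, 1, 0, 0, 2, 4),
    moved_stigma = c(0, 3, 0, 0, 2, 2))
  for (o in outs) expect_equal(tr$rows[[o]], expected_race[[o]])
})

test_that("rows are lexicographic, partition n, and ignore record order", {
  for (seed in 1:10) {
    df <- rand_participants(40, seed + 900)
    tt <- build_truth_table(df, identity_conditions)
    expect_equal(sum(tt$rows$count), nrow(df))
    keys <- apply(as.matrix(tt$rows[, identity_conditions]), 1, paste,
                  collapse = "")
    expect_equal(keys, sort(keys))
    # complementary identity flags never co-occur in a configuration
    expect_true(all(tt$rows$lgb + tt$rows$straight <= 1))
    # permuting records leaves the table unchanged
    perm <- df[sample(nrow(df)), ]
    tt_perm <- build_truth_table(perm, identity_conditions)
    expect_equal(tt_perm$rows, tt$rows)
  }
})

test_that("a single record gives one row with degenerate percentages", {
  one <- rand_participants(1, 31)
  tt <- build_truth_table(one, identity_conditions)
  expect_equal(nrow(tt$rows), 1)
  expect_equal(tt$rows$count, 1L)
  for (o in tt$outcomes) {
    expect_true(consistency(tt, o)[[1]] %in% c(0, 1))
  }
})

test_that("min_freq drops rare configurations but keeps exact coverage", {
  df <- rand_participants(40, 77)
  tt1 <- build_truth_table(df, identity_conditions, min_freq = 1)
  tt3 <- build_truth_table(df, identity_conditions, min_freq = 3)
  expect_true(all(tt3$rows$count >= 3))
  expect_true(nrow(tt3$rows) <= nrow(tt1$rows))
  # coverage still sums to 1 over all observed configurations
  o <- "called_names"
  if (sum(df[[o]]) > 0) {
    covs <- vapply(seq_len(nrow(tt1$rows)), function(i) {
      coverage(tt3, as.integer(tt1$rows[i, identity_conditions]), o)
    }, 0)
    expect_equal(sum(covs), 1)
  }
})

test_that("consistency matches the filter-and-count proportion", {
  fx <- cached_fixture()
  tt <- build_truth_table(fx, identity_conditions)
  expect_equal(consistency(tt, "called_names", c(1, 1, 1, 0)), 5 / 7)
  expect_equal(round_half_up(100 * consistency(tt, "called_names",
                                               c(1, 1, 1, 0)), 1), 71.4)
  # an all-absent outcome row has consistency 0
  expect_equal(consistency(tt, "work_unfair", c(0, 0, 0, 1)), 0)

  for (seed in 1:15) {
    df <- rand_participants(30, seed + 1100)
    tt <- build_truth_table(df, race_conditions)
    for (i in seq_len(nrow(tt$rows))) {
      cfg <- as.integer(tt$rows[i, race_conditions])
      expect_equal(consistency(tt, "moved_stigma", cfg),
                   oracle_consistency(df, race_conditions, cfg,
                                      "moved_stigma"))
    }
  }
})

test_that("coverage is the outcome-conditional configuration share", {
  # outcome occurring only inside one configuration has coverage 1
  df <- rand_participants(12, 55)
  cat <- default_catalog()
  for (id in cat$id) df[[id]] <- 0L
  df$moved_stigma[df$people_told >= 3] <- 1L
  df$informed_sex_partners[df$people_told >= 3] <- 1L
  df$informed_sex_partners[df$people_told < 3] <- 0L
  df$sexual_identity <- "gay_lesbian"
  tt <- build_truth_table(df, identity_conditions)
  expect_equal(coverage(tt, c(1, 1, 1, 0), "moved_stigma"), 1)

  for (seed in 1:15) {
    dfr <- rand_participants(30, seed + 1300)
    tt <- build_truth_table(dfr, identity_conditions)
    o <- "friends_reject"
    if (sum(dfr[[o]]) == 0) {
      expect_error(coverage(tt, c(1, 1, 1, 0), o), "undefined")
      next
    }
    covs <- vapply(seq_len(nrow(tt$rows)), function(i) {
      cfg <- as.integer(tt$rows[i, identity_conditions])
      expect_equal(coverage(tt, cfg, o),
                   oracle_coverage(dfr, identity_conditions, cfg, o))
      coverage(tt, cfg, o)
    }, 0)
    expect_equal(sum(covs), 1)  # observed configurations partition cases
  }
})

test_that("identify_consistent returns exactly the rows at threshold", {
  fx <- cached_fixture()
  tt <- build_truth_table(fx, identity_conditions)
  hit <- identify_consistent(tt, "friends_reject", threshold = 1.0)
  expect_equal(nrow(hit), 1)
  expect_equal(as.integer(hit[1, identity_conditions]), c(1L, 1L, 0L, 1L))
  expect_equal(hit$count, 2L)

  # a tiny threshold keeps every row with at least one endorsing case
  eps <- identify_consistent(tt, "called_names", threshold = 1e-9)
  expect_equal(nrow(eps), sum(tt$rows$called_names > 0))
  expect_error(identify_consistent(tt, "called_names", threshold = 0),
               "proportion")
  expect_error(identify_consistent(tt, "called_names", threshold = 1.2),
               "proportion")

  for (seed in 1:10) {
    df <- rand_participants(25, seed + 1500)
    tt <- build_truth_table(df, race_conditions)
    th <- 0.5
    hit <- identify_consistent(tt, "called_names", th)
    manual <- vapply(seq_len(nrow(tt$rows)), function(i) {
      oracle_consistency(df, race_conditions,
                         as.integer(tt$rows[i, race_conditions]),
                         "called_names") >= th
    }, TRUE)
    expect_equal(nrow(hit), sum(manual))
  }
})

test_that("condition sets are validated", {
  df <- rand_participants(10, 2)
  expect_error(build_truth_table(df, c("told3plus")), "2 and 5")
  expect_error(build_truth_table(df, rep("told3plus", 2)), "distinct")
  expect_error(build_truth_table(df, c("told3plus", "eye_colour")),
               "eye_colour")
  expect_error(
    build_truth_table(df, identity_conditions, outcomes = "nope"), "nope")
})
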