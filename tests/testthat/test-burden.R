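test_that("fixture group burden means reproduce the published values", {
  gm <- group_mean_burden(cached_fixture())
  g <- function(x) gm[gm$group == x, ]
  expect_equal(g("high_partner")$n, 9L)
  expect_equal(round_half_up(g("high_partner")$mean_burden, 1), 9.3)
  expect_equal(g("low_nopartner")$n, 7L)
  expect_equal(round_half_up(g("low_nopartner")$mean_burden, 1), 6.6)
  expect_equal(g("high_nopartner")$n, 1L)
  expect_equal(g("high_nopartner")$mean_burden, 3.0)
  # nobody informed partners while disclosing narrowly
  expect_equal(g("low_partner")$n, 0L)
  expect_true(is.na(g("low_partner")$mean_burden))
})

test_that("group means match brute-force averages and recover the total", {
  for (seed in 1:25) {
    df <- rand_participants(sample(4:50, 1), seed + 300)
    gm <- group_mean_burden(df)
    orc <- oracle_group_means(df)
    expect_equal(setNames(gm$n, as.character(gm$group)), orc$n)
    expect_equal(setNames(gm$mean_burden, as.character(gm$group)), orc$mean)
    # n-weighted group means recover the overall burden total
    expect_equal(sum(gm$total_burden), sum(isolation_score(df)))
  }
  one <- rand_participants(1, 9)
  gm1 <- group_mean_burden(one)
  expect_equal(gm1$mean_burden[gm1$n == 1], isolation_score(one))
})

test_that("domain profiles are double means over domain items", {
  df <- rand_participants(20, 4)
  cat <- default_catalog()
  zero <- df
  for (id in cat$id) zero[[id]] <- 0L
  for (g in levels(disclosure_group(derive_flags(zero)))) {
    members <- sum(as.character(disclosure_group(derive_flags(zero))) == g)
    if (members == 0) next
    expect_equal(domain_profile(zero, g)$value, rep(0, 7))
  }
  one <- df
  for (id in cat$id) one[[id]] <- 1L
  g <- as.character(disclosure_group(derive_flags(one)))[1]
  expect_equal(domain_profile(one, g)$value, rep(1, 7))

  for (seed in 1:10) {
    dfr <- rand_participants(30, seed + 500)
    grp <- as.character(disclosure_group(derive_flags(dfr)))[1]
    prof <- domain_profile(dfr, grp)
    expect_true(all(prof$value >= 0 & prof$value <= 1))
    for (d in domain_labels()) {
      expect_equal(prof$value[prof$domain == d],
                   oracle_domain_value(dfr, grp, d))
    }
  }

  narrow <- df
  narrow$people_told <- 0L
  narrow$informed_sex_partners <- 0L
  expect_error(domain_profile(narrow, "high_partner"), "empty")
})

test_that("fixture heatmap cells reproduce the published counts", {
  hm <- indicator_heatmap(cached_fixture())
  cell <- function(g, i) hm[hm$group == g & hm$indicator == i, ]
  c1 <- cell("told3plus", "called_names")
  expect_equal(c(c1$count, c1$n), c(7L, 10L))
  expect_equal(round_half_up(c1$percent, 0), 70)
  c2 <- cell("informed_sex_partners", "work_unfair")
  expect_equal(c(c2$count, c2$n), c(6L, 9L))
  expect_equal(round_half_up(c2$percent, 0), 67)
  c3 <- cell("white", "called_names")
  expect_equal(c(c3$count, c3$n), c(3L, 3L))
  expect_equal(c3$percent, 100)
  c4 <- cell("gay_or_lesbian", "called_names")
  expect_equal(c(c4$count, c4$n), c(9L, 11L))
  expect_equal(round_half_up(c4$percent, 0), 82)
})

test_that("heatmap tallies equal membership-and-indicator loops", {
  flags <- c("told3plus", "informed_sex_partners", "gay_or_lesbian",
             "straight", "black", "white")
  for (seed in 1:10) {
    df <- rand_participants(35, seed + 700)
    hm <- indicator_heatmap(df)
    for (g in flags) {
      for (ind in c("called_names", "housing_trouble", "not_part_lgbt")) {
        orc <- oracle_heatmap_cell(df, g, ind)
        row <- hm[hm$group == g & hm$indicator == ind, ]
        expect_equal(row$count, orc$count)
        expect_equal(row$n, orc$n)
      }
    }
  }
  # empty subgroup: flagged by n = 0, percent undefined
  allb <- rand_participants(6, 12)
  allb$race <- "black"
  hm <- indicator_heatmap(allb)
  wrow <- hm[hm$group == "white", ]
  expect_true(all(wrow$n == 0))
  expect_true(all(is.na(wrow$percent)))
})

test_that("scatter data caps, jitters within bounds, and is seed-stable", {
  df <- rand_participants(30, 8)
  df$people_told[1] <- 25L
  sc <- prepare_scatter(df, jitter_seed = 123)
  expect_equal(sc$points$x_capped[1], 10L)
  expect_equal(sc$points$x_raw[1], 25L)
  expect_equal(sc$points$y, isolation_score(df))
  expect_true(all(abs(sc$points$x_jit - sc$points$x_capped) <= 0.15))
  expect_true(all(abs(sc$points$y_jit - sc$points$y) <= 0.15))
  expect_equal(sc$x_median, median(pmin(df$people_told, 10)))
  expect_equal(sc$y_threshold, 7L)
  # same seed, identical output; different seed, different jitter
  expect_identical(sc, prepare_scatter(df, jitter_seed = 123))
  sc2 <- prepare_scatter(df, jitter_seed = 124)
  expect_false(identical(sc$points$x_jit, sc2$points$x_jit))
})
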