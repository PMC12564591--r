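test_that("default catalog satisfies the instrument invariants", {
  cat <- default_catalog()
  expect_silent(validate_catalog(cat))
  expect_equal(nrow(cat), 15)
  expect_setequal(unique(cat$domain), domain_labels())
  expect_setequal(cat$id[cat$qca_outcome],
                  c("family_rejects", "friends_reject", "called_names",
                    "work_unfair", "moved_stigma"))
  # the LGBT-belonging item is the one stored reverse-coded
  expect_true(cat$reverse_coded[cat$id == "not_part_lgbt"])
})

test_that("catalog validation rejects malformed instruments", {
  cat <- default_catalog()
  expect_error(validate_catalog(cat[-1, ]), "15 items")
  bad <- cat
  bad$domain[1] <- "School"
  expect_error(validate_catalog(bad), "unknown domain")
  bad <- cat
  bad$qca_outcome[cat$id == "moved_stigma"] <- FALSE
  expect_error(validate_catalog(bad), "qca_outcome")
  bad <- cat
  bad$id[2] <- bad$id[1]
  expect_error(validate_catalog(bad), "unique")
})

test_that("catalog YAML round-trips identically", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_catalog(default_catalog(), path)
  expect_equal(read_catalog(path), default_catalog())
})

test_that("participant CSV write/read is the identity on random data", {
  for (seed in c(3, 11)) {
    df <- rand_participants(25, seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_participants(df, path)
    back <- read_participants(path)
    expect_equal(back, df)
  }
  # empty table round-trips as a header-only CSV
  empty <- generate_random(synthetic_params(n = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_participants(empty, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_participants(path)), 0)
})

test_that("schema violations are reported with the offending column or row", {
  df <- rand_participants(5, 1)
  path <- withr::local_tempfile(fileext = ".csv")

  miss <- df[, setdiff(names(df), "housing_trouble")]
  readr::write_csv(miss, path)
  expect_error(read_participants(path), "housing_trouble")

  extra <- df
  extra$notes <- "x"
  readr::write_csv(extra, path)
  suppressWarnings(expect_error(read_participants(path), "notes"))

  bad <- df
  bad$called_names[3] <- 2
  readr::write_csv(bad, path)
  expect_error(read_participants(path), bad$pid[3])

  bad <- df
  bad$work_unfair[2] <- NA
  readr::write_csv(bad, path)
  expect_error(read_participants(path), "work_unfair")

  bad <- df
  bad$sexual_identity[1] <- "queer"
  readr::write_csv(bad, path)
  expect_error(read_participants(path), "sexual_identity")
})

test_that("derived flags honour the inclusive thresholds and partitions", {
  df <- rand_participants(40, 5)
  cfg <- threshold_config()
  fl <- derive_flags(df, cfg)

  expect_equal(fl$told3plus, as.integer(df$people_told >= 3))
  # boundary: telling exactly 3 people counts as broad disclosure
  two <- df
  two$people_told <- rep(c(2L, 3L), 20)
  fl2 <- derive_flags(two, cfg)
  expect_equal(fl2$told3plus, rep(c(0L, 1L), 20))

  # identity flags partition the sample; race flags never overlap
  expect_equal(fl$lgb + fl$straight, rep(1L, 40))
  expect_true(all(fl$gay_or_lesbian <= fl$lgb))
  expect_true(all(fl$black + fl$white <= 1))

  # deterministic: same inputs, same flags
  expect_identical(fl, derive_flags(df, cfg))
})

test_that("the fixture has the published demographic margins", {
  fx <- cached_fixture()
  expect_equal(nrow(fx), 17)
  expect_equal(sum(fx$race == "black"), 13)
  expect_equal(sum(fx$race == "white"), 3)
  fl <- derive_flags(fx)
  expect_equal(sum(fl$told3plus), 10)
  expect_equal(sum(fl$informed_sex_partners), 9)

  # and survives a CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_participants(fx, path)
  expect_equal(read_participants(path), fx)
})
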