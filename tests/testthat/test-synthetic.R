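test_that("the compiled ledger is complete and machine-checkable", {
  led <- compile_ledger()
  expect_s3_class(led, "constraint_ledger")
  # spot-check headline entries
  expect_equal(led$target[led$id == "isolated_count"], 10)
  expect_equal(led$target[led$id == "tt_identity_1101_count"], 2)
  expect_equal(led$target[led$id == "burden_sum_high_partner"], 84)
  # every entry evaluates to a definite pass/fail on any candidate dataset
  any_df <- rand_participants(8, 3)
  chk <- check_ledger(any_df)
  expect_false(anyNA(chk$observed))
  expect_type(chk$pass, "logical")
})

test_that("the fixture solver is deterministic and ledger-satisfying", {
  fx <- cached_fixture()
  chk <- check_ledger(fx)
  expect_true(all(chk$pass))
  expect_identical(fx, build_fixture(seed = 42))
  # a different seed still satisfies every constraint
  fx2 <- cached_fixture(7)
  expect_true(all(check_ledger(fx2)$pass))
})

test_that("flipping any single indicator bit violates the ledger", {
  fx <- cached_fixture()
  led <- compile_ledger()
  cat <- default_catalog()
  # every flip perturbs at least one exact count or burden-sum constraint;
  # scan all 17 x 15 bits and record which constraints each flip breaks
  violations <- list()
  for (i in seq_len(nrow(fx))) {
    for (id in cat$id) {
      mut <- fx
      mut[[id]][i] <- 1L - mut[[id]][i]
      chk <- check_ledger(mut, led)
      broken <- chk$id[!chk$pass]
      expect_gt(length(broken), 0)
      violations[[paste(fx$pid[i], id)]] <- broken
    }
  }
  # flips of a burden-coded bit always disturb the group's burden sum
  expect_true(all(vapply(violations,
                         function(b) any(grepl("burden_sum", b)), TRUE)))
})

test_that("the generator is reproducible and validates its parameters", {
  p <- synthetic_params(n = 30, seed = 11)
  expect_identical(generate_random(p), generate_random(p))
  expect_equal(nrow(generate_random(synthetic_params(n = 0))), 0)
  expect_error(synthetic_params(told_probs = rep(0.2, 11)), "sum to 1")
  expect_error(synthetic_params(p_informed_high = 1.4), "\\[0, 1\\]")
  expect_error(
    synthetic_params(identity_probs = c(gay_lesbian = 0.5, straight = 0.5)),
    "identity_probs")
})

test_that("empirical prevalences recover the parameters at n = 2000", {
  n <- 2000
  ci <- function(p) stats::qbinom(c(0.005, 0.995), n, p) / n

  flat <- generate_random(
    synthetic_params(n = n, indicator_prevalence = 0.4,
                     condition_flag = NULL, seed = 21))
  for (id in c("called_names", "housing_trouble", "lgbt_excluded")) {
    emp <- mean(flat[[id]])
    bounds <- ci(0.4)
    expect_gte(emp, bounds[1])
    expect_lte(emp, bounds[2])
  }

  # subgroup-conditioned prevalence is recovered within each subgroup
  cond <- generate_random(
    synthetic_params(n = n, condition_flag = "told3plus",
                     prevalence_when_1 = 0.7, prevalence_when_0 = 0.3,
                     seed = 22))
  high <- cond$people_told >= 3
  for (id in c("family_rejects", "work_excluded")) {
    emp_hi <- mean(cond[[id]][high])
    emp_lo <- mean(cond[[id]][!high])
    expect_gte(emp_hi, stats::qbinom(0.005, sum(high), 0.7) / sum(high))
    expect_lte(emp_hi, stats::qbinom(0.995, sum(high), 0.7) / sum(high))
    expect_gte(emp_lo, stats::qbinom(0.005, sum(!high), 0.3) / sum(!high))
    expect_lte(emp_lo, stats::qbinom(0.995, sum(!high), 0.3) / sum(!high))
  }

  # category probabilities drive subgroup composition
  expect_gt(mean(cond$race == "black"), 0.66)
  expect_lt(mean(cond$race == "black"), 0.86)
})
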