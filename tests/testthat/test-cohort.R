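test_that("gestational-age parsing round-trips and validates", {
  cases <- list(
    list(text = "25 + 4", weeks = 25L, days = 4L, dec = 25 + 4 / 7),
    list(text = "40 + 0", weeks = 40L, days = 0L, dec = 40),
    list(text = "39+6", weeks = 39L, days = 6L, dec = 39 + 6 / 7)
  )
  for (cs in cases) {
    ga <- parse_gest_age(cs$text)
    expect_identical(ga_weeks(ga), cs$weeks)
    expect_identical(ga_days(ga), cs$days)
    expect_equal(ga_decimal_weeks(ga), cs$dec, tolerance = 1e-9)
    # decimal form round-trips through parsing to the same day
    expect_identical(unclass(parse_gest_age(sprintf("%.6f", cs$dec))),
                     unclass(ga))
  }
  expect_error(parse_gest_age("40 + 7"), "days")
  expect_error(gest_age(30, -1), "days")
  expect_error(gest_age(-1, 0), "weeks")
  expect_error(parse_gest_age("not an age"), "parse")
})

test_that("GAMRI arithmetic is exact day arithmetic", {
  expect_identical(format(compute_gamri(gest_age(40, 0), 14)), "42 + 0")
  expect_identical(format(compute_gamri(gest_age(39, 6), 17)), "42 + 2")
  expect_identical(format(compute_gamri(gest_age(25, 4), 0)), "25 + 4")
  expect_error(compute_gamri(gest_age(30, 0), -1), "postnatal")
  # associativity with day addition
  set.seed(1)
  for (i in 1:20) {
    ga <- gest_age(sample(23:41, 1), sample(0:6, 1))
    d1 <- sample(0:60, 1); d2 <- sample(0:60, 1)
    expect_identical(
      unclass(compute_gamri(compute_gamri(ga, d1), d2)),
      unclass(compute_gamri(ga, d1 + d2)))
  }
})

test_that("group allocation is a step function at exactly 37 weeks", {
  expect_identical(allocate_group(gest_age(36, 6)), "preterm")
  expect_identical(allocate_group(gest_age(37, 0)), "term")
  expect_identical(allocate_group(gest_age(25, 4)), "preterm")
  ages <- gest_age(rep(22:43, each = 7), rep(0:6, times = 22))
  expect_identical(allocate_group(ages),
                   ifelse(ga_decimal_weeks(ages) < 37, "preterm", "term"))
})

test_that("inclusion filter reproduces combined-reason accounting", {
  roster <- flagged_roster(25L)
  filt <- apply_inclusion_filter(roster)
  expect_equal(filt$report$n_total, 30)
  expect_equal(filt$report$n_included, 25)
  expect_equal(filt$report$inclusion_rate_percent, 100 * 25 / 30)
  expect_equal(unname(filt$report$reasons),
               c(1, 3, 1))  # motion-only, devastation-only, both
  # the doubly flagged subject appears exactly once among the excluded
  expect_equal(nrow(filt$excluded), 5)
  expect_equal(sum(duplicated(filt$excluded$subject_id)), 0)
  # idempotence and partition
  again <- apply_inclusion_filter(filt$included)
  expect_identical(as.data.frame(again$included),
                   as.data.frame(filt$included))
  expect_equal(nrow(filt$included) + nrow(filt$excluded), nrow(roster))
})

test_that("no flags means everyone is included", {
  co <- simulate_cohort(cohort_sim_config(seed = 3))
  filt <- apply_inclusion_filter(co)
  expect_equal(filt$report$n_included, nrow(co))
  expect_equal(nrow(filt$excluded), 0)
})

test_that("cohort simulation is deterministic and matches its config", {
  cfg <- cohort_sim_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), cfg$n_preterm + cfg$n_term)
  expect_false(anyDuplicated(a$subject_id) > 0)
  # group always re-derived from the drawn birth age
  expect_identical(a$group,
                   allocate_group(gest_age(a$ga_weeks, a$ga_days)))
  # gamri consistency
  gamri <- compute_gamri(gest_age(a$ga_weeks, a$ga_days), a$postnatal_days)
  expect_identical(a$gamri_weeks, ga_weeks(gamri))
  expect_identical(a$gamri_days, ga_days(gamri))
})

test_that("sampled gestational ages match the configured distribution", {
  # mean over many draws stays within 3 * sd / sqrt(n) of the target
  cfg <- cohort_sim_config(n_preterm = 18L, n_term = 0L, seed = 7)
  reps <- do.call(rbind, lapply(1:12, function(i) {
    cfg$seed <- i
    as.data.frame(simulate_cohort(cfg))
  }))
  ga_dec <- reps$ga_weeks + reps$ga_days / 7
  n <- nrow(reps)
  expect_lt(abs(mean(ga_dec) - cfg$preterm$ga_mean_weeks),
            3 * cfg$preterm$ga_sd_weeks / sqrt(n))
  expect_true(all(ga_dec >= 22 & ga_dec <= 42))
  expect_true(all(reps$postnatal_days >= 0))
})

test_that("cohort CSV round-trips losslessly", {
  co <- simulate_cohort(cohort_sim_config(seed = 9, p_devastation = 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co), ignore_attr = TRUE)
  expect_error(read_cohort_csv(file.path(tempdir(), "nope.csv")),
               "not found")
})
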