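# Microdata estimators against loop-based tally oracles.

test_that("age schedule estimates union shares and fertility rates", {
  rec <- make_records(age_group = rep(age_group_labels(), each = 10),
                      in_union = rep(c(rep(TRUE, 4), rep(FALSE, 6)), 7))
  sched <- estimate_age_schedule(rec, window_years = 3)
  expect_equal(unname(sched$m), rep(0.4, 7))

  rec2 <- make_records(age_group = rep(age_group_labels(), each = 5),
                       births_in_window = rep(c(2, 1, 0, 0, 0), 7))
  sched2 <- estimate_age_schedule(rec2, window_years = 3)
  expect_equal(unname(sched2$g), rep(3 / (5 * 3), 7))

  # weighted 14-record fixture vs the brute-force tally
  rec3 <- make_records(age_group = rep(age_group_labels(), each = 2),
                       in_union = rep(c(TRUE, FALSE), 7),
                       births_in_window = rep(c(1, 2), 7),
                       weight = rep(c(0.5, 1.5), 7))
  sched3 <- estimate_age_schedule(rec3, window_years = 3)
  orc <- oracle_age_schedule(rec3, 3)
  expect_equal(unname(sched3$m), orc$m)
  expect_equal(unname(sched3$g), orc$g)

  expect_error(estimate_age_schedule(make_records(age_group = "20-24")),
               "15-19")
})

test_that("tfr_from_schedule is five times the rate sum", {
  expect_equal(tfr_from_schedule(age_schedule(rep(0.5, 7), rep(0, 7))), 0)
  expect_equal(tfr_from_schedule(age_schedule(rep(0.5, 7), rep(0.1, 7))), 3.5)
  g <- c(0.08, 0.18, 0.19, 0.16, 0.12, 0.06, 0.02)
  expect_equal(tfr_from_schedule(age_schedule(rep(0.5, 7), g)), 5 * sum(g))
})

test_that("method mix partitions prevalence among in-union women", {
  rec <- all_groups_records()
  mix0 <- estimate_method_mix(rec)
  expect_equal(mix0$u, 0)
  expect_true(all(mix0$shares == 0))

  meth <- c(rep("pill", 20), rep("injection", 16), rep("none", 64))
  rec2 <- make_records(age_group = rep(age_group_labels(), length.out = 100),
                       in_union = TRUE, method = meth)
  mix2 <- estimate_method_mix(rec2)
  expect_equal(mix2$u, 0.36)
  expect_equal(mix2$shares[["pill"]], 0.20)
  expect_equal(mix2$shares[["injection"]], 0.16)

  expect_error(estimate_method_mix(make_records(in_union = FALSE)),
               "no in-union women")
})

test_that("mean amenorrhea averages reported durations for recent births", {
  rec <- make_records(age_group = rep(age_group_labels(), each = 2),
                      births_in_window = 1, amenorrhea_months = 12)
  expect_equal(mean_amenorrhea(rec), 12)

  rec2 <- make_records(age_group = c("20-24", "25-29"), births_in_window = 1,
                       amenorrhea_months = c(6, 18))
  expect_equal(mean_amenorrhea(rec2), 12)

  # weighted fixture vs oracle; NA rows excluded as structural missingness
  rec3 <- make_records(age_group = rep("20-24", 4),
                       births_in_window = c(1, 2, 0, 1),
                       amenorrhea_months = c(6, 18, NA, 10),
                       weight = c(1, 2, 5, 0.5))
  expect_equal(mean_amenorrhea(rec3), oracle_mean_amenorrhea(rec3))
  expect_equal(mean_amenorrhea(rec3), (6 + 2 * 18 + 0.5 * 10) / 3.5)

  expect_error(mean_amenorrhea(make_records()), "no women with a birth")
})

test_that("total foetal wastage mirrors the TFR identity", {
  expect_equal(total_fetal_wastage(all_groups_records(), 3), 0)
  # 50 women per group, 3 events each group: rate 3/150 = 0.02/woman-year
  rec <- make_records(age_group = rep(age_group_labels(), each = 50),
                      wastage_in_window = rep(c(rep(1, 3), rep(0, 47)), 7))
  expect_equal(total_fetal_wastage(rec, 3), 5 * 7 * 0.02)
  expect_equal(total_fetal_wastage(rec, 3), 0.7)
})

test_that("every estimator agrees with the tally oracle on random tables", {
  for (seed in 1:20) {
    rec <- random_records_full(sample(30:100, 1), seed)
    orc_s <- oracle_age_schedule(rec, 3)
    sched <- estimate_age_schedule(rec, 3)
    expect_equal(unname(sched$m), orc_s$m)
    expect_equal(unname(sched$g), orc_s$g)
    orc_m <- oracle_method_mix(rec)
    mix <- estimate_method_mix(rec)
    expect_equal(mix$u, orc_m$u)
    expect_equal(unname(mix$shares), unname(orc_m$shares))
    expect_equal(sum(mix$shares), mix$u, tolerance = 1e-12)
    if (any(rec$births_in_window > 0 & !is.na(rec$amenorrhea_months))) {
      expect_equal(mean_amenorrhea(rec), oracle_mean_amenorrhea(rec))
    }
    expect_equal(total_fetal_wastage(rec, 3), oracle_tfw(rec, 3))
  }
})

test_that("estimates are invariant to a constant weight rescaling", {
  rec <- random_records_full(80, 99)
  for (k in c(0.25, 7)) {
    rescaled <- rec
    rescaled$weight <- rec$weight * k
    a <- estimate_indices(rec)
    b <- estimate_indices(rescaled)
    expect_equal(unlist(a[c("Cm", "Cc", "Ci", "Cfw", "tfr_model")]),
                 unlist(b[c("Cm", "Cc", "Ci", "Cfw", "tfr_model")]))
  }
})

test_that("stratum tallies add up to the whole-population tallies", {
  rec <- random_records_full(120, 5)
  whole <- as.data.frame(rec)
  split_sum <- function(df, col) {
    agg <- tapply(df$weight * df[[col]], factor(df$age_group, age_group_labels()),
                  sum, default = 0)
    as.numeric(agg)
  }
  for (v in c("region", "residence", "wealth_quintile")) {
    parts <- lapply(split(whole, whole[[v]]), split_sum, col = "births_in_window")
    expect_equal(Reduce(`+`, parts), split_sum(whole, "births_in_window"))
    wparts <- lapply(split(whole, whole[[v]]), function(d) sum(d$weight))
    expect_equal(Reduce(`+`, wparts), sum(whole$weight))
  }
})

test_that("estimate_indices assembles the bundle and surfaces preconditions", {
  # zero-prevalence population: Cc is exactly 1
  rec <- make_records(age_group = rep(age_group_labels(), each = 4),
                      in_union = TRUE, births_in_window = 1,
                      amenorrhea_months = 10)
  res <- estimate_indices(rec)
  expect_identical(res$Cc, 1)
  expect_equal(res$Cm, 1)
  expect_equal(res$inputs$tfr_obs, tfr_from_schedule(estimate_age_schedule(rec, 3)))

  # all-unmarried, no births: fails through the marriage-index path
  bad <- make_records(age_group = rep(age_group_labels(), each = 2),
                      in_union = FALSE)
  expect_error(estimate_indices(bad), "\\[index_marriage\\]")
})

test_that("woman_records enforces the schema", {
  expect_error(woman_records(data.frame(age_group = "20-24")), "missing column")
  df <- as.data.frame(make_records())
  df$method <- "pill"
  df$in_union <- FALSE
  expect_error(woman_records(df), "requires in_union")
  df2 <- as.data.frame(make_records())
  df2$age_group <- "50-54"
  expect_error(woman_records(df2), "unknown age_group")
  df3 <- as.data.frame(make_records())
  df3$weight <- 0
  expect_error(woman_records(df3), "weights must be positive")
})

test_that("woman records round-trip through CSV", {
  rec <- random_records_full(40, 3)
  path <- tempfile(fileext = ".csv")
  write_woman_records(rec, path)
  back <- read_woman_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})
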