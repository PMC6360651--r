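# Closed-form index formulas, composition, decomposition, projection.

asfr <- c(0.08, 0.18, 0.19, 0.16, 0.12, 0.06, 0.02)  # a plausible schedule

test_that("index_marriage is the fertility-weighted mean of m(a)", {
  expect_equal(index_marriage(age_schedule(rep(1, 7), asfr)), 1)
  expect_equal(index_marriage(age_schedule(rep(0.5, 7), asfr)), 0.5)

  # frozen from the direct weighted-average oracle: sum(m*g)/sum(g)
  m <- c(0.1, 0.4, 0.7, 0.8, 0.8, 0.7, 0.6)
  g <- c(0.05, 0.20, 0.25, 0.20, 0.12, 0.05, 0.01)
  expect_equal(round(index_marriage(age_schedule(m, g)), 4), 0.6330)

  expect_error(index_marriage(age_schedule(rep(0.5, 7), rep(0, 7))),
               "no fertility in schedule")
})

test_that("index_marriage stays within [min m, max m] on random schedules", {
  set.seed(41)
  for (k in 1:200) {
    m <- runif(7)
    g <- rgamma(7, 2, 10)
    cm <- index_marriage(age_schedule(m, g))
    expect_gte(cm, min(m))
    expect_lte(cm, max(m))
  }
})

test_that("mean use-effectiveness weights the method mix", {
  expect_equal(mean_use_effectiveness(method_mix(0.3, c(pill = 0.3))), 0.90)
  expect_equal(mean_use_effectiveness(method_mix(0.4, c(pill = 0.2, IUD = 0.2))),
               0.925)
  expect_equal(mean_use_effectiveness(method_mix(0.1, c(sterilization = 0.1))),
               1.00)
  expect_error(mean_use_effectiveness(method_mix(0, numeric(0))),
               "undefined when prevalence is zero")
  # bounds under the default table, any mix
  set.seed(7)
  for (k in 1:50) {
    sh <- runif(5)
    u <- runif(1, 0.05, 1)
    sh <- sh / sum(sh) * u
    names(sh) <- c("pill", "IUD", "sterilization", "injection", "other")
    e <- mean_use_effectiveness(method_mix(u, sh))
    expect_gte(e, 0.70)
    expect_lte(e, 1.00)
  }
})

test_that("index_contraception matches the published projection factors", {
  expect_equal(index_contraception(0, 0.9), 1)
  expect_equal(round(index_contraception(0.36, 0.933), 3), 0.637)
  expect_equal(round(index_contraception(0.55, 0.933), 3), 0.446)
  expect_warning(cc <- index_contraception(1, 1), class = "pd_index_out_of_range")
  expect_lt(cc, 0)
  expect_error(index_contraception(1.2, 0.5), "u must lie")
})

test_that("index_postpartum follows 20/(18.5+i)", {
  expect_identical(index_postpartum(1.5), 1)
  expect_equal(round(index_postpartum(12.13), 3), 0.653)
  expect_warning(ci0 <- index_postpartum(0), class = "pd_index_out_of_range")
  expect_equal(round(as.numeric(ci0), 3), 1.081)
  expect_error(index_postpartum(-1), "non-negative")
})

test_that("foetal wastage: AFW formula and Cfw ratio", {
  expect_equal(averted_fetal_wastage(0.5, 0), 0)
  expect_equal(averted_fetal_wastage(0, 1), 0.4)
  expect_equal(round(averted_fetal_wastage(0.35, 0.777), 4), 0.4196)

  expect_equal(index_fetal_wastage(3, 0), 1)
  expect_equal(round(index_fetal_wastage(4.14, 0.4196), 3), 0.908)
  expect_equal(index_fetal_wastage(1, 1), 0.5)
  expect_error(index_fetal_wastage(0, 0.1), "TFR must be positive")
})

test_that("indices are strictly monotone in their drivers", {
  u <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(vapply(u, index_contraception, numeric(1), e = 0.9)) < 0))
  e <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(vapply(e, index_contraception, numeric(1), u = 0.4)) < 0))
  i <- seq(1.5, 24, by = 0.5)
  expect_true(all(diff(vapply(i, index_postpartum, numeric(1))) < 0))
  afw <- seq(0, 2, by = 0.1)
  expect_true(all(diff(vapply(afw, index_fetal_wastage, numeric(1),
                              tfr_obs = 4)) < 0))
})

test_that("composition multiplies the four indices into TF", {
  expect_equal(compose_tfr(1, 1, 1, 1, 15.3), 15.3)
  expect_equal(round(compose_tfr(0.656, 0.693, 0.655, 0.908, 15.3), 2), 4.14)
  expect_equal(round(compose_tfr(0.648, 0.639, 0.590, 0.888, 15.3), 3), 3.319)
  expect_error(compose_tfr(0.5, 0.5, 0.5, 0.5, -1), "TF must be positive")
})

test_that("proximate_indices stores a self-consistent composed TFR", {
  set.seed(11)
  for (k in 1:100) {
    v <- runif(4, 0.05, 1)
    tf <- runif(1, 10, 20)
    pi_ <- proximate_indices(v[1], v[2], v[3], v[4], tf)
    expect_equal(pi_$tfr_model,
                 compose_tfr(pi_$Cm, pi_$Cc, pi_$Ci, pi_$Cfw, pi_$TF),
                 tolerance = 1e-12)
    expect_length(pi_$flags, 0)
  }
  flagged <- proximate_indices(0.5, 0.5, 1.08, 0.9)
  expect_identical(flagged$flags, "Ci")
})

test_that("percent inhibition reproduces the published decomposition", {
  expect_equal(percent_inhibition(1), 0)
  expect_equal(round(percent_inhibition(0.622), 1), 37.8)
  expect_equal(round(percent_inhibition(0.908), 1), 9.2)
  expect_error(percent_inhibition(0), "in \\(0, 1\\]")
})

test_that("projection scales the baseline TFR by the Cc ratio", {
  expect_equal(project_tfr(4.6, 0.36, 0.36, 0.933), 4.6)
  expect_equal(round(project_tfr(4.6, 0.36, 0.55, 0.933), 1), 3.2)
  # frozen from direct arithmetic: 5*(1-1.08*.4*.9)/(1-1.08*.2*.9)
  expect_equal(round(project_tfr(5, 0.2, 0.4, 0.9), 3), 3.793)
  expect_error(project_tfr(4, 0.95, 0.5, 1), "not positive")
})

test_that("swapped projection scenarios invert exactly", {
  set.seed(19)
  for (k in 1:50) {
    u1 <- runif(1, 0, 0.8); u2 <- runif(1, 0, 0.8)
    e1 <- runif(1, 0.5, 1); e2 <- runif(1, 0.5, 1)
    tfr1 <- runif(1, 1, 8)
    fwd <- project_tfr(tfr1, u1, u2, e1, e2)
    expect_equal(project_tfr(fwd, u2, u1, e2, e1), tfr1, tolerance = 1e-12)
  }
})

test_that("config validates and round-trips through JSON", {
  cfg <- pd_config(tf = 14, sterility_adjustment = 1.1)
  expect_equal(cfg$tf, 14)
  expect_error(pd_config(effectiveness = c(pill = 2)), "must name all")
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(tf = 14.5, rounding = list(percent = 2)),
                       path, auto_unbox = TRUE)
  cfg2 <- read_pd_config(path)
  expect_equal(cfg2$tf, 14.5)
  expect_equal(cfg2$rounding$percent, 2)
  expect_equal(cfg2$rounding$index, 3L)  # untouched default
  expect_error(read_pd_config({
    p <- tempfile(fileext = ".json")
    jsonlite::write_json(list(bogus = 1), p, auto_unbox = TRUE); p
  }), "unknown config fields")
})
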