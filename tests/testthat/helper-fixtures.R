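# Fixture builders and independent loop-based tally oracles. The oracles
# deliberately re-derive every quantity row by row, never calling the
# package estimators.

make_records <- function(age_group = "20-24", in_union = TRUE,
                         births_in_window = 0, method = "none",
                         amenorrhea_months = NA_real_, wastage_in_window = 0,
                         region = "all", wealth_quintile = "all",
                         education = "all", residence = "all", weight = 1) {
  woman_records(data.frame(
    age_group = age_group, in_union = in_union,
    births_in_window = births_in_window, method = method,
    amenorrhea_months = amenorrhea_months,
    wastage_in_window = wastage_in_window,
    region = region, wealth_quintile = wealth_quintile,
    education = education, residence = residence, weight = weight))
}

# one woman per cell across all 7 age groups, so estimator preconditions hold
all_groups_records <- function(...) {
  base <- make_records(age_group = rep(age_group_labels(), each = 2), ...)
  base
}

random_records <- function(n, seed) {
  set.seed(seed)
  in_union <- runif(n) < 0.6
  method <- rep("none", n)
  users <- in_union & runif(n) < 0.4
  method[users] <- sample(c("pill", "IUD", "sterilization", "injection", "other"),
                          sum(users), replace = TRUE)
  births <- rpois(n, 0.5)
  amen <- ifelse(births > 0, round(runif(n, 0, 24), 1), NA_real_)
  woman_records(data.frame(
    age_group = sample(age_group_labels(), n, replace = TRUE),
    in_union = in_union, births_in_window = births, method = method,
    amenorrhea_months = amen, wastage_in_window = rpois(n, 0.1),
    region = sample(c("A", "B"), n, replace = TRUE),
    wealth_quintile = sample(c("Lowest", "Highest"), n, replace = TRUE),
    education = "all",
    residence = sample(c("Urban", "Rural"), n, replace = TRUE),
    weight = round(runif(n, 0.5, 2), 3)))
}

# ensure every age group is present (random_records at small n may miss one)
random_records_full <- function(n, seed) {
  rec <- random_records(max(n, 14L), seed)
  missing <- setdiff(age_group_labels(), unique(rec$age_group))
  if (length(missing)) {
    rec <- woman_records(rbind(as.data.frame(rec),
                               as.data.frame(make_records(age_group = missing))))
  }
  rec
}

oracle_age_schedule <- function(df, window_years) {
  m <- g <- numeric(7)
  for (k in seq_along(age_group_labels())) {
    rows <- df[df$age_group == age_group_labels()[k], , drop = FALSE]
    m[k] <- sum(rows$weight * rows$in_union) / sum(rows$weight)
    g[k] <- sum(rows$weight * rows$births_in_window) /
      (sum(rows$weight) * window_years)
  }
  list(m = m, g = g)
}

oracle_method_mix <- function(df) {
  inu <- df[df$in_union, , drop = FALSE]
  methods <- c("pill", "IUD", "sterilization", "injection", "other")
  shares <- numeric(length(methods))
  for (k in seq_along(methods)) {
    shares[k] <- sum(inu$weight[inu$method == methods[k]]) / sum(inu$weight)
  }
  names(shares) <- methods
  list(u = sum(shares), shares = shares)
}

oracle_mean_amenorrhea <- function(df) {
  rows <- df[df$births_in_window > 0 & !is.na(df$amenorrhea_months), , drop = FALSE]
  sum(rows$weight * rows$amenorrhea_months) / sum(rows$weight)
}

oracle_tfw <- function(df, window_years) {
  rates <- numeric(7)
  for (k in seq_along(age_group_labels())) {
    rows <- df[df$age_group == age_group_labels()[k], , drop = FALSE]
    rates[k] <- sum(rows$weight * rows$wastage_in_window) /
      (sum(rows$weight) * window_years)
  }
  5 * sum(rates)
}
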