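rt <- load_rate_table()
pw <- load_model_parameters("female")
pm <- load_model_parameters("male")

high_risk_woman <- list(SKINCOLOUR = "fair", MOLES_RARM = "3+",
                        FAMHXMOLES = "yes", NMSC = "yes")

test_that("combined relative risk is the product of the profile's odds ratios", {
  expect_equal(combined_relative_risk(pw, high_risk_woman),
               4.50 * 4.28 * 2.62 * 3.75)
  # all-reference profiles sit at 1 for both sexes
  expect_equal(combined_relative_risk(pw, list(
    SKINCOLOUR = "olive", MOLES_RARM = "0", FAMHXMOLES = "don't know",
    NMSC = "no")), 1)
  expect_equal(combined_relative_risk(pm, list(
    AGE = "<=50", OCC18 = "indoor", MOLES_RARM = 0,
    BIRTHPLACE = "outside NZ", NMSC = "no")), 1)
  # male over-50 low-risk profile, with AGE derived from exact age
  expect_equal(combined_relative_risk(pm, list(
    age = 60, OCC18 = "indoor", MOLES_RARM = 0,
    BIRTHPLACE = "outside NZ", NMSC = "no")), 2.59)
  # count variable enters as per-unit OR to the power of the count
  expect_equal(combined_relative_risk(pm, list(
    AGE = "<=50", OCC18 = "indoor", MOLES_RARM = 3,
    BIRTHPLACE = "outside NZ", NMSC = "no")), 1.15^3)
})

test_that("profiles outside the schema are rejected, extreme counts warned", {
  expect_error(combined_relative_risk(pw, list(
    SKINCOLOUR = "tan", MOLES_RARM = "0", FAMHXMOLES = "no", NMSC = "no")),
    "not valid for SKINCOLOUR")
  expect_error(combined_relative_risk(pw, list(SKINCOLOUR = "fair")),
               "missing variable")
  expect_warning(combined_relative_risk(pm, list(
    AGE = "<=50", OCC18 = "indoor", MOLES_RARM = 25,
    BIRTHPLACE = "in NZ", NMSC = "no")), "plausible")
})

test_that("Bruzzi attributable risk has its closed forms and stratum identity", {
  refs <- data.frame(SKINCOLOUR = "olive", MOLES_RARM = "0",
                     FAMHXMOLES = "don't know", NMSC = "no")
  all_ref <- refs[rep(1, 10), ]
  expect_equal(attributable_risk(all_ref, pw)$ar, 0)

  # all cases at a single stratum with r = 4.50 * ... is 1 - 1/r; use a
  # two-stratum mix and check against the explicit stratum formula
  cases <- rbind(all_ref[1:4, ],
                 data.frame(SKINCOLOUR = "fair", MOLES_RARM = "0",
                            FAMHXMOLES = "don't know", NMSC = "no")[rep(1, 6), ])
  est <- attributable_risk(cases, pw)
  expect_equal(est$ar, 1 - (0.4 / 1 + 0.6 / 4.50))
  expect_equal(sum(est$strata$rho), 1)
  expect_equal(est$strata$rr, c(1, 4.50))
  expect_error(attributable_risk(refs[0, ], pw), "at least one case")
})

test_that("the estimator matches the exact enumeration of the generating model", {
  cfg <- default_sim_config("female")
  truth <- enumerate_disease_model(cfg)
  pop <- generate_population(cfg, 200000, seed = 55)
  cases <- pop[pop$status == 1L, ]
  est <- attributable_risk(cases, pw)$ar
  # Monte-Carlo SE of 1 - mean(1/r) over the sampled cases
  inv_r <- vapply(seq_len(nrow(cases)), function(i)
    1 / combined_relative_risk(pw, cases[i, ]), numeric(1))
  mc_se <- sd(inv_r) / sqrt(length(inv_r))
  expect_lt(abs(est - truth$bruzzi_target), 3 * mc_se)
  # and the Bruzzi target itself agrees with the population-count oracle
  # 1 - (incidence in the all-reference stratum) / (overall incidence)
  # up to the rare-disease odds-vs-risk gap
  pop_ar <- 1 - truth$p_disease_reference / truth$p_disease
  expect_lt(abs(truth$bruzzi_target - pop_ar), 0.02)
})

test_that("bootstrap AR is seeded and degenerates gracefully at B=2", {
  cfg <- default_sim_config("female")
  dat <- simulate_case_control(cfg, seed = 60, pop_size = 40000)
  a <- bootstrap_ar(dat, pw, B = 30, seed = 2)
  b <- bootstrap_ar(dat, pw, B = 30, seed = 2)
  expect_identical(a, b)
  expect_true(a$ci[1] <= a$ar && a$ar <= a$ci[2])

  smoke <- bootstrap_ar(dat, pw, B = 2, seed = 5)
  expect_length(smoke$replicates, 2)
  expect_equal(smoke$se, sd(smoke$replicates))
})

test_that("baseline hazard discounts incidence by the attributable risk", {
  expect_equal(baseline_hazard(174.31, 0.89), 19.1741)
  expect_equal(baseline_hazard(174.31, 0), 174.31)
  expect_equal(baseline_hazard(0, 0.89), 0)
  expect_error(baseline_hazard(10, 1))
})

test_that("single-band absolute risk has the closed form and its limits", {
  # zero competing mortality, one band: pi = 1 - exp(-tau * r * h1)
  df <- as.data.frame(rt)
  df$mortality_per_100k <- 0
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE, na = "")
  rt0 <- load_rate_table(tmp)
  res <- absolute_risk(rt0, "female", "Midland", 80, rr = 189.38, ar = 0.89)
  h1 <- 174.31e-5 * 0.11
  expect_equal(res$pi, 1 - exp(-5 * 189.38 * h1), tolerance = 1e-12)

  # as AR -> 1 the melanoma hazard vanishes and pi -> 0 at rate r*h1*tau
  res0 <- absolute_risk(rt, "female", "Midland", 80, rr = 189.38, ar = 1 - 1e-9)
  expect_lt(res0$pi, 5 * 189.38 * 0.0017431 * 1e-9)
  df$incidence_per_100k <- 0
  write.csv(df, tmp, row.names = FALSE, na = "")
  rt00 <- load_rate_table(tmp)
  expect_equal(absolute_risk(rt00, "male", "North", 40, rr = 5, ar = 0)$pi, 0)

  # small-hazard limit: pi ~ tau * r * h1
  tiny <- absolute_risk(rt, "female", "Central", 20, rr = 1, ar = 0.89)
  approx <- 5 * 1 * 8.57e-5 * 0.11
  expect_lt(abs(tiny$pi - approx) / approx, 0.01)
})

test_that("band decomposition sums to the total and splitting bands changes nothing", {
  res <- absolute_risk(rt, "male", "Midland", 42, rr = 12, ar = 0.85)
  expect_equal(sum(res$bands$contribution), res$pi)
  expect_true(all(res$bands$contribution >= 0))
  expect_equal(sum(res$bands$width), 5)
  expect_equal(nrow(res$bands), 2)   # 42 spans 40-44 and 45-49

  # split each 5-year band into single years with identical rates
  df <- as.data.frame(rt)
  split_rows <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    if (is.na(row$age_high)) return(row)
    out <- row[rep(1, row$age_high - row$age_low + 1), ]
    out$age_low <- row$age_low:row$age_high
    out$age_high <- out$age_low
    out
  }))
  tmp <- tempfile(fileext = ".csv")
  write.csv(split_rows, tmp, row.names = FALSE, na = "")
  rt_split <- load_rate_table(tmp)
  for (age in c(20, 42, 61.5, 80)) {
    a <- absolute_risk(rt, "male", "Midland", age, rr = 12, ar = 0.85)
    b <- absolute_risk(rt_split, "male", "Midland", age, rr = 12, ar = 0.85)
    expect_equal(a$pi, b$pi, tolerance = 1e-12)
  }
})

test_that("absolute risk is monotone in horizon and relative risk, anti-monotone in mortality", {
  pis <- sapply(1:10, function(tau)
    absolute_risk(rt, "female", "North", 47, rr = 20, ar = 0.89,
                  horizon = tau)$pi)
  expect_true(all(diff(pis) > 0))
  pis_r <- sapply(c(1, 2, 5, 20, 100), function(r)
    absolute_risk(rt, "female", "North", 47, rr = r, ar = 0.89)$pi)
  expect_true(all(diff(pis_r) > 0))
  expect_true(all(pis >= 0 & pis <= 1))

  df <- as.data.frame(rt)
  df$mortality_per_100k <- df$mortality_per_100k * 3
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE, na = "")
  rt_hi <- load_rate_table(tmp)
  expect_lt(absolute_risk(rt_hi, "female", "North", 47, rr = 20, ar = 0.89)$pi,
            absolute_risk(rt, "female", "North", 47, rr = 20, ar = 0.89)$pi)
})

test_that("projection past the last closed band falls back to the open band", {
  expect_message(
    res <- absolute_risk(rt, "female", "South", 83, rr = 10, ar = 0.89),
    "85\\+")
  expect_equal(nrow(res$bands), 2)
  expect_equal(res$bands$band_low, c(80, 85))
  expect_error(absolute_risk(rt, "female", "South", 40, rr = 1, ar = 0,
                             horizon = -1), "horizon")
  expect_error(absolute_risk(rt, "female", "South", 15, rr = 1, ar = 0),
               "below the supported")
})

test_that("profile-driven absolute risk matches the rr-driven path", {
  r <- combined_relative_risk(pw, high_risk_woman)
  a <- absolute_risk(rt, "female", "Midland", 80, params = pw,
                     profile = high_risk_woman)
  b <- absolute_risk(rt, "female", "Midland", 80, rr = r, ar = 0.89)
  expect_equal(a$pi, b$pi)
  expect_equal(a$rr, r)
  expect_equal(a$ar, 0.89)
})

test_that("risk_table evaluates grids, singletons and empty grids", {
  grid <- data.frame(sex = c("female", "male"),
                     age = c(80, 60), region = c("Midland", "Midland"),
                     rr = c(189.38, 2.59))
  tab <- risk_table(rt, grid, params_female = pw, params_male = pm)
  expect_equal(nrow(tab), 2)
  single <- absolute_risk(rt, "female", "Midland", 80, rr = 189.38,
                          ar = 0.89)
  expect_equal(tab$risk[1], single$pi)

  empty <- risk_table(rt, grid[0, ], params_female = pw, params_male = pm)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("risk", "risk_pct") %in% names(empty)))
})
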