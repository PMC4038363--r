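test_that("chi-square equals the published candidate-table statistics", {
  # statistics computed from the printed case/control counts, no
  # continuity correction, 2 dp
  expect_equal(round(chi_square_test(
    cbind(c(57, 82), c(93, 89)))$statistic, 2), 3.22)
  expect_equal(round(chi_square_test(
    cbind(c(22, 53, 64), c(7, 57, 118)))$statistic, 2), 18.50)
  expect_equal(chi_square_test(cbind(c(22, 53, 64), c(7, 57, 118)))$df, 2)
  # identical row proportions give exactly 0
  expect_equal(chi_square_test(cbind(c(10, 20), c(30, 60)))$statistic, 0)
})

test_that("chi-square matches brute-force sum((O-E)^2/E) on random tables", {
  set.seed(1)
  for (i in 1:25) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    tab <- matrix(rpois(r * c, 20) + 1, r, c)
    expect_equal(chi_square_test(tab)$statistic, brute_chi_square(tab))
  }
})

test_that("chi-square rejects degenerate tables", {
  expect_error(chi_square_test(matrix(c(1, 2), 1)), "at least 2")
  expect_error(chi_square_test(cbind(c(0, 0), c(3, 4))), "zero row or column")
  expect_error(chi_square_test(cbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("univariate screening types variables correctly and applies the threshold", {
  set.seed(5)
  cfg <- default_sim_config("male", intercept = -4)
  pop <- generate_population(cfg, 40000, seed = 31)
  scr <- univariate_screen(pop, c("OCC18", "MOLES_RARM", "NMSC"),
                           types = default_variable_types("male"))
  expect_identical(scr$test[scr$variable == "MOLES_RARM"], "wald_logistic")
  expect_identical(scr$test[scr$variable == "OCC18"], "chi_square")
  # per-mole generating OR 1.15 recovered and retained at the 0.25 screen
  or <- scr$odds_ratio[scr$variable == "MOLES_RARM"]
  expect_gt(or, 1.05)
  expect_lt(or, 1.27)
  expect_true(all(scr$retained))

  # threshold 1 retains everything by definition
  scr_all <- univariate_screen(pop, c("OCC18", "NMSC"), threshold = 1)
  expect_true(all(scr_all$retained))
  expect_error(univariate_screen(pop, "NOPE"), "absent")
})

test_that("a null covariate at n=300 is rarely retained at the 0.25 screen", {
  retained <- 0L
  for (s in 1:40) {
    set.seed(400 + s)
    d <- data.frame(status = rbinom(300, 1, 0.4),
                    X = sample(c("a", "b"), 300, TRUE))
    scr <- univariate_screen(d, "X")
    retained <- retained + scr$retained
  }
  # null p-values are uniform: retention rate should be near 25%, not 50%+
  expect_lt(retained / 40, 0.5)
})

test_that("saturated 2x2 logistic fit equals the cross-product odds ratio", {
  d <- dataset_2x2(30, 25, 12, 40)
  fit <- fit_logistic(d, "X", refs = list(X = "no"))
  or_hat <- fit$coef_table$odds_ratio[fit$coef_table$level == "yes"]
  expect_equal(or_hat, (30 * 40) / (25 * 12), tolerance = 1e-6)
  # reference level carried as an exact zero
  expect_identical(fit$coef_table$beta[fit$coef_table$level == "no"], 0)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$logLik)
})

test_that("small-fit log-likelihood matches a coarse-grid maximisation", {
  set.seed(8)
  d <- data.frame(status = rbinom(30, 1, 0.5), x = rnorm(30))
  fit <- fit_logistic(d, "x", types = c(x = "count"))
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * d$x)
    sum(d$status * log(p) + (1 - d$status) * log(1 - p))
  }
  # nested golden-section maximisation, independent of glm's IRLS
  neg_profile <- function(b1) {
    optimize(function(b0) -ll(b0, b1), c(-6, 6), tol = 1e-10)$objective
  }
  best <- -optimize(neg_profile, c(-6, 6), tol = 1e-10)$objective
  expect_equal(fit$logLik, best, tolerance = 1e-6)
})

test_that("fit reports missing status and single-class outcomes", {
  d <- dataset_2x2(5, 5, 5, 5)
  expect_error(fit_logistic(d[d$status == 1, ], "X"), "both cases and controls")
  expect_error(fit_logistic(data.frame(X = 1:5), "X"), "no status column")
})

test_that("backward selection keeps the active variable and drops null ones", {
  cfg <- default_sim_config("female", intercept = -3)
  # only SKINCOLOUR carries signal
  for (v in setdiff(names(cfg$variables), "SKINCOLOUR")) {
    cfg$variables[[v]]$odds_ratios <-
      rep(1, length(cfg$variables[[v]]$odds_ratios))
  }
  cands <- c("SKINCOLOUR", "NMSC", "FAMHXMOLES", "SUNBURN")
  picked_signal <- 0L
  null_inclusions <- 0L
  n_seeds <- 8L
  for (s in seq_len(n_seeds)) {
    pop <- generate_population(cfg, 20000, seed = 500 + s)
    sel <- backward_select(pop, cands,
                           refs = list(SKINCOLOUR = "olive"))
    picked_signal <- picked_signal + ("SKINCOLOUR" %in% sel$selected)
    null_inclusions <- null_inclusions +
      length(setdiff(sel$selected, "SKINCOLOUR"))
    # dropping a variable never increases the log-likelihood: the trace's
    # LR statistics are all non-negative
    expect_true(all(sel$trace$lr_statistic >= -1e-8))
  }
  expect_equal(picked_signal, n_seeds)
  # each null variable survives with probability ~stay_p
  expect_lt(null_inclusions / (3 * n_seeds), 0.35)
})

test_that("strong effects are never dropped, and directions agree on strong-signal data", {
  cfg <- default_sim_config("female", intercept = -3.5)
  pop <- generate_population(cfg, 30000, seed = 77)
  cands <- c("SKINCOLOUR", "MOLES_RARM", "FAMHXMOLES", "NMSC")
  refs <- list(SKINCOLOUR = "olive", MOLES_RARM = "0",
               FAMHXMOLES = "don't know", NMSC = "no")
  back <- backward_select(pop, cands, refs = refs)
  expect_setequal(back$selected, cands)
  expect_equal(nrow(back$trace), 0)
  fwd <- forward_select(pop, cands, refs = refs)
  expect_setequal(fwd$selected, back$selected)
  expect_error(backward_select(pop, character(0)), "empty candidate")
})

test_that("bootstrap selection stability is seeded, bounded, and ranks the dominant predictor first", {
  cfg <- default_sim_config("female", intercept = -2.5)
  for (v in setdiff(names(cfg$variables), "SKINCOLOUR")) {
    cfg$variables[[v]]$odds_ratios <-
      rep(1, length(cfg$variables[[v]]$odds_ratios))
  }
  cfg$variables$SKINCOLOUR$odds_ratios <- c(1, 4, 8)
  pop <- generate_population(cfg, 4000, seed = 90)
  dat <- sample_case_control(pop, 250, 250, matched = FALSE, seed = 91)
  cands <- c("SKINCOLOUR", "NMSC", "SUNBURN")
  rep1 <- bootstrap_selection_stability(dat, cands, B = 25, seed = 7)
  rep2 <- bootstrap_selection_stability(dat, cands, B = 25, seed = 7)
  expect_identical(rep1, rep2)
  freq <- setNames(rep1$inclusion_frequency, rep1$variable)
  expect_true(all(freq >= 0 & freq <= 1))
  expect_gt(freq[["SKINCOLOUR"]], max(freq[c("NMSC", "SUNBURN")]))

  b1 <- bootstrap_selection_stability(dat, cands, B = 1, seed = 3)
  expect_true(all(b1$inclusion_frequency %in% c(0, 1)))
})
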