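# Independent oracles used across tests. These deliberately avoid the
# package's own computation paths.

# Brute-force Pearson chi-square: sum (O - E)^2 / E over all cells.
brute_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Exhaustive pair-counting C-statistic.
brute_c_statistic <- function(p, y) {
  cases <- p[y == 1]
  ctrls <- p[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# Fine-grid RK4 integration of the two-cause competing-risk system:
#   S'(t)  = -(r h1(t) + h2(t)) S(t)
#   Pi'(t) =  r h1(t) S(t)
# with piecewise-constant hazards looked up from the rate table. The time
# grid is broken at the hazard discontinuities (5-year band edges) so the
# integrator never steps across a jump.
ode_absolute_risk <- function(rates, sex, region, age, rr, ar,
                              horizon = 5, steps_per_piece = 100) {
  edges <- c(seq(25, 85, 5), Inf)
  knots <- sort(unique(c(0, horizon,
                         edges[edges > age & edges < age + horizon] - age)))
  deriv <- function(t, state) {
    lk <- lookup_rates(rates, sex, region, age + t)
    h1 <- rr * lk$incidence * (1 - ar)
    c(-(h1 + lk$mortality) * state[1], h1 * state[1])
  }
  state <- c(1, 0)
  for (i in seq_len(length(knots) - 1)) {
    dt <- (knots[i + 1] - knots[i]) / steps_per_piece
    t <- knots[i]
    for (s in seq_len(steps_per_piece)) {
      # evaluate hazards strictly inside the piece
      tm <- t + dt / 2
      k1 <- deriv(tm, state)
      k2 <- deriv(tm, state + dt / 2 * k1)
      k3 <- deriv(tm, state + dt / 2 * k2)
      k4 <- deriv(tm, state + dt * k3)
      state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + dt
    }
  }
  state[2]
}

# Exact enumeration of the synthetic-cohort disease model for a config with
# categorical variables only: joint covariate probabilities and disease
# probabilities per stratum. Returns the marginal disease probability, the
# all-reference stratum's disease probability, and the Bruzzi target
# 1 - sum_j P(j | case) / RR_j computed from the generating odds ratios.
enumerate_disease_model <- function(config) {
  vars <- config$variables
  stopifnot(all(vapply(vars, function(v) v$type == "categorical",
                       logical(1))))
  grids <- lapply(vars, function(v) seq_along(v$levels))
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  p_x <- rep(1, nrow(combos))
  log_rr <- rep(0, nrow(combos))
  for (j in seq_along(vars)) {
    v <- vars[[j]]
    p_x <- p_x * v$prevalences[combos[[j]]]
    log_rr <- log_rr + log(v$odds_ratios)[combos[[j]]]
  }
  # the age-group effect enters through the pyramid margin
  p50 <- {
    ab <- config$age_bands
    w <- ab$weight / sum(ab$weight)
    # share of each band above 50 (ages uniform within 5-year bands)
    sum(w * pmin(pmax((ab$high + 1 - 50) / 5, 0), 1))
  }
  age_or <- config$age_over50_or
  p_dis <- function(extra_or) {
    stats::plogis(config$intercept + log_rr + log(extra_or))
  }
  pd_le <- p_dis(1)
  pd_gt <- p_dis(age_or)
  p_d_given_x <- (1 - p50) * pd_le + p50 * pd_gt
  p_d <- sum(p_x * p_d_given_x)
  rr <- exp(log_rr)                 # generating RR vs all-reference combo
  # case distribution over (stratum, age group)
  p_case_le <- p_x * (1 - p50) * pd_le / p_d
  p_case_gt <- p_x * p50 * pd_gt / p_d
  bruzzi_target <- 1 - sum(p_case_le / rr) - sum(p_case_gt / (rr * age_or))
  ref <- which(log_rr == 0)[1]
  list(p_disease = p_d,
       p_disease_reference = (1 - p50) * pd_le[ref] + p50 * pd_gt[ref],
       bruzzi_target = bruzzi_target)
}

# Small deterministic case-control dataset with a single binary covariate
# laid out from a 2x2 table (a, b = exposed/unexposed cases; c, d =
# exposed/unexposed controls).
dataset_2x2 <- function(a, b, c, d) {
  data.frame(
    status = rep(c(1L, 1L, 0L, 0L), c(a, b, c, d)),
    X = rep(c("yes", "no", "yes", "no"), c(a, b, c, d)),
    stringsAsFactors = FALSE)
}
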