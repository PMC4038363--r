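#' Combined relative risk for a risk-factor profile
#'
#' Multiplies the profile's per-variable odds ratios (relative risks under
#' the rare-disease approximation): categorical variables contribute their
#' level's OR, count variables the per-unit OR raised to the count. An
#' all-reference profile has combined relative risk 1.
#'
#' For male profiles the dichotomous \code{AGE} group may be given directly
#' or derived from an \code{age} entry (cut at 50).
#'
#' @param params a \code{model_params} object
#'   (\code{\link{load_model_parameters}}).
#' @param profile named list (or one-row data frame) of covariate values;
#'   count variables as non-negative integers.
#' @return the combined relative risk (scalar).
#' @export
#' @examples
#' pw <- load_model_parameters("female")
#' combined_relative_risk(pw, list(SKINCOLOUR = "fair", MOLES_RARM = "3+",
#'                                 FAMHXMOLES = "yes", NMSC = "yes"))
combined_relative_risk <- function(params, profile) {
  stopifnot(inherits(params, "model_params"))
  profile <- as.list(profile)
  if (!"AGE" %in% names(profile) && "AGE" %in% names(params$variables) &&
      "age" %in% names(profile)) {
    profile$AGE <- if (profile$age <= 50) "<=50" else ">50"
  }
  r <- 1
  for (v in params$variables) {
    val <- profile[[v$name]]
    if (is.null(val) || is.na(val)) {
      stop("profile is missing variable ", v$name, call. = FALSE)
    }
    if (v$type == "categorical") {
      val <- as.character(val)
      if (!val %in% v$levels) {
        stop("level '", val, "' is not valid for ", v$name,
             " (expected one of: ", paste(v$levels, collapse = ", "), ")",
             call. = FALSE)
      }
      r <- r * v$odds_ratios[[val]]
    } else {
      val <- as.numeric(val)
      if (val < 0 || val != round(val)) {
        stop(v$name, " must be a non-negative integer count", call. = FALSE)
      }
      if (val > 20) {
        warning(v$name, " = ", val,
                " is beyond the plausible observed range (> 20)",
                call. = FALSE)
      }
      r <- r * v$per_unit_odds_ratio^val
    }
  }
  r
}

#' Combined relative risks for many profiles at once
#'
#' Vectorised companion to \code{\link{combined_relative_risk}}: computes
#' the odds-ratio product for every row of a data frame of profiles.
#'
#' @param params a \code{model_params} object.
#' @param profiles data frame with one row per profile.
#' @return numeric vector of combined relative risks.
#' @export
profile_relative_risks <- function(params, profiles) {
  stopifnot(inherits(params, "model_params"))
  n <- nrow(profiles)
  log_r <- numeric(n)
  for (v in params$variables) {
    if (!v$name %in% names(profiles)) {
      if (v$name == "AGE" && "age" %in% names(profiles)) {
        profiles$AGE <- ifelse(profiles$age <= 50, "<=50", ">50")
      } else {
        stop("profiles are missing variable ", v$name, call. = FALSE)
      }
    }
    val <- profiles[[v$name]]
    if (anyNA(val)) {
      stop("missing value in variable ", v$name, call. = FALSE)
    }
    if (v$type == "categorical") {
      idx <- match(as.character(val), v$levels)
      if (anyNA(idx)) {
        bad <- as.character(val)[which(is.na(idx))[1]]
        stop("level '", bad, "' is not valid for ", v$name, call. = FALSE)
      }
      log_r <- log_r + log(v$odds_ratios)[idx]
    } else {
      val <- as.numeric(val)
      if (any(val < 0 | val != round(val))) {
        stop(v$name, " must be non-negative integer counts", call. = FALSE)
      }
      log_r <- log_r + val * log(v$per_unit_odds_ratio)
    }
  }
  exp(log_r)
}

#' Bruzzi case-based attributable risk
#'
#' Estimates the fraction of cases attributable to the modelled risk
#' factors from the cases' exposure distribution and the model's relative
#' risks: \eqn{AR = 1 - \sum_j \rho_j / RR_j}, where \eqn{\rho_j} is the
#' proportion of cases in joint exposure stratum \eqn{j} and \eqn{RR_j} its
#' relative risk versus the all-reference stratum. Computed case-wise as
#' \eqn{1 - \mathrm{mean}_i(1/r_i)}, which is algebraically identical.
#'
#' @param cases data frame of case covariate records (one row per case;
#'   must carry the variables in \code{params}).
#' @param params a \code{model_params} object.
#' @return an \code{ar_estimate}: the AR, n cases, and the per-stratum
#'   summary (\code{rho}, \code{rr}).
#' @export
attributable_risk <- function(cases, params) {
  cases <- as.data.frame(cases)
  if (!nrow(cases)) stop("at least one case profile required", call. = FALSE)
  r <- profile_relative_risks(params, cases)
  if (any(r <= 0)) stop("all relative risks must be > 0", call. = FALSE)
  strata <- stats::aggregate(list(n = r), by = list(rr = r), FUN = length)
  strata$rho <- strata$n / nrow(cases)
  structure(list(ar = 1 - mean(1 / r), n_cases = nrow(cases),
                 strata = strata[order(strata$rr), c("rr", "rho", "n")]),
            class = "ar_estimate")
}

#' @export
print.ar_estimate <- function(x, ...) {
  cat("Bruzzi attributable risk: ", format(x$ar, digits = 4),
      " (", x$n_cases, " cases, ", nrow(x$strata),
      " exposure strata)\n", sep = "")
  invisible(x)
}

# Rebuild a model_params object from a fitted case-control logistic model
# (ORs = exp(beta), reference levels at OR 1), so the AR can be
# re-estimated from refitted models.
params_from_fit <- function(fit, sex = "female", attributable_risk = 0) {
  stopifnot(inherits(fit, "cc_fit"))
  vars <- lapply(fit$variables, function(v) {
    ct <- fit$coef_table[fit$coef_table$variable == v, ]
    if (identical(ct$level, "(per unit)")) {
      list(name = v, type = "count", per_unit_odds_ratio = ct$odds_ratio)
    } else {
      list(name = v, type = "categorical", levels = ct$level,
           reference = ct$level[abs(ct$beta) < 1e-12][1],
           odds_ratios = stats::setNames(ct$odds_ratio, ct$level))
    }
  })
  names(vars) <- fit$variables
  structure(list(sex = sex, attributable_risk = attributable_risk,
                 variables = vars), class = "model_params")
}

#' Bootstrap uncertainty for the attributable risk
#'
#' Nonparametric bootstrap of the Bruzzi AR. In \code{"fixed-params"} mode
#' only the cases are resampled and the supplied relative risks are held
#' fixed; in \code{"refit"} mode cases and controls are resampled within
#' arm and the logistic model is refitted on each resample before the AR is
#' recomputed, propagating model uncertainty.
#'
#' @param data case-control data frame with \code{status} and the model
#'   variables.
#' @param params a \code{model_params} (used directly in fixed mode; in
#'   refit mode it supplies the variable schema and reference levels).
#' @param B number of bootstrap resamples (at least 2).
#' @param mode \code{"fixed-params"} or \code{"refit"}.
#' @param types,refs variable typing/reference levels for refitting.
#' @param seed integer RNG seed.
#' @return list with the point estimate, bootstrap \code{se}, percentile
#'   \code{ci} (2.5/97.5%), the replicate values, and the count of redrawn
#'   degenerate resamples.
#' @export
bootstrap_ar <- function(data, params, B = 200L,
                         mode = c("fixed-params", "refit"),
                         types = NULL, refs = NULL, seed = 1L) {
  stopifnot(B >= 2)
  mode <- match.arg(mode)
  set.seed(seed)
  model_vars <- names(params$variables)
  idx_case <- which(data$status == 1L)
  idx_ctrl <- which(data$status == 0L)
  if (!length(idx_case)) stop("no cases in dataset", call. = FALSE)
  inv_r <- 1 / profile_relative_risks(params,
                                      data[idx_case, , drop = FALSE])
  point <- 1 - mean(inv_r)
  reps <- numeric(B)
  redraws <- 0L
  if (is.null(refs)) {
    refs <- lapply(params$variables, function(v)
      if (v$type == "categorical") v$reference else NULL)
  }
  for (b in seq_len(B)) {
    repeat {
      take <- sample.int(length(idx_case), length(idx_case),
                         replace = TRUE)
      ci <- idx_case[take]
      val <- tryCatch({
        if (mode == "fixed-params") {
          1 - mean(inv_r[take])
        } else {
          ti <- c(ci, sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
          fit <- fit_logistic(data[ti, ], model_vars, types, refs)
          if (!fit$converged) stop("degenerate resample")
          bp <- params_from_fit(fit, params$sex)
          attributable_risk(data[ci, model_vars, drop = FALSE], bp)$ar
        }
      }, error = function(e) NULL)
      if (!is.null(val) && is.finite(val)) break
      redraws <- redraws + 1L
      if (redraws > 50L * B) {
        stop("too many degenerate bootstrap resamples", call. = FALSE)
      }
    }
    reps[b] <- val
  }
  list(ar = point, se = stats::sd(reps),
       ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE),
       replicates = reps, redraws = redraws, B = B, mode = mode)
}

#' Baseline hazard for an all-reference individual
#'
#' Discounts the population incidence hazard by the attributable risk:
#' \eqn{h_1 = I \times (1 - AR)}, the incidence among people with none of
#' the modelled risk factors.
#'
#' @param incidence population incidence hazard (any consistent rate unit).
#' @param ar attributable risk in [0, 1).
#' @return baseline hazard in the same unit as \code{incidence}.
#' @export
baseline_hazard <- function(incidence, ar) {
  stopifnot(all(incidence >= 0), ar < 1, ar >= 0)
  incidence * (1 - ar)
}

# Partition [age, age + horizon) at the rate table's band boundaries.
band_partition <- function(rates, sex, region, age, horizon) {
  cuts <- age
  t <- age
  end <- age + horizon
  repeat {
    band <- lookup_rates(rates, sex, region, t)
    nxt <- if (is.na(band$age_high)) Inf else band$age_high + 1
    if (nxt >= end) break
    cuts <- c(cuts, nxt)
    t <- nxt
  }
  data.frame(start = cuts, width = diff(c(cuts, end)))
}

#' Five-year absolute risk of melanoma under competing mortality
#'
#' Projects the probability of a first melanoma within \code{horizon} years
#' for an individual, combining their combined relative risk \eqn{r}, the
#' AR-discounted baseline incidence \eqn{h_1}, and competing non-melanoma
#' mortality \eqn{h_2}, all piecewise constant on the rate table's age
#' bands. Splitting \eqn{[a, a+\tau)} at band boundaries into intervals
#' \eqn{k} of width \eqn{\Delta_k}:
#' \deqn{\pi = \sum_k \frac{r h_{1k}}{r h_{1k} + h_{2k}}
#'   \exp\!\Big(-\sum_{j<k} \Delta_j (r h_{1j} + h_{2j})\Big)
#'   \big(1 - e^{-\Delta_k (r h_{1k} + h_{2k})}\big),}
#' i.e. the probability melanoma strikes first in interval \eqn{k}, summed
#' over intervals. Intervals with zero total hazard contribute zero.
#' Projection beyond the table's last closed band uses the open (85+) band.
#'
#' @param rates a \code{rate_table}.
#' @param sex,region,age the individual's sex, region and exact age
#'   (years, at least 20).
#' @param params a \code{model_params}; supplies the attributable risk and,
#'   with \code{profile}, the relative risk.
#' @param profile covariate profile (see
#'   \code{\link{combined_relative_risk}}); ignored when \code{rr} is given.
#' @param rr optional combined relative risk, overriding \code{profile}
#'   (useful for published profile RRs).
#' @param ar optional attributable risk override.
#' @param horizon projection horizon in years (default 5).
#' @return an \code{absolute_risk} object: probability \code{pi}, \code{rr},
#'   \code{ar}, horizon, and the per-interval decomposition (band, width,
#'   baseline and mortality hazards, contribution).
#' @export
#' @examples
#' rt <- load_rate_table()
#' pw <- load_model_parameters("female")
#' absolute_risk(rt, "female", "Midland", 80, params = pw,
#'               profile = list(SKINCOLOUR = "fair", MOLES_RARM = "3+",
#'                              FAMHXMOLES = "yes", NMSC = "yes"))
absolute_risk <- function(rates, sex, region, age, params = NULL,
                          profile = NULL, rr = NULL, ar = NULL,
                          horizon = 5) {
  if (horizon <= 0) stop("projection horizon must be > 0", call. = FALSE)
  if (age < 20) {
    stop("age ", age, " is below the supported range (20+)", call. = FALSE)
  }
  if (is.null(rr)) {
    if (is.null(params) || is.null(profile)) {
      stop("either rr or both params and profile must be supplied",
           call. = FALSE)
    }
    rr <- combined_relative_risk(params, c(as.list(profile), age = age))
  }
  if (is.null(ar)) {
    if (is.null(params)) {
      stop("ar must be supplied when params is not", call. = FALSE)
    }
    ar <- params$attributable_risk
  }
  part <- band_partition(rates, sex, region, age, horizon)
  surv <- 1
  rows <- lapply(seq_len(nrow(part)), function(k) {
    rt <- lookup_rates(rates, sex, region, part$start[k])
    h1 <- baseline_hazard(rt$incidence, ar)
    a <- rr * h1 + rt$mortality
    data.frame(start = part$start[k], width = part$width[k],
               band_low = rt$age_low, h1 = h1, h2 = rt$mortality,
               total_hazard = a)
  })
  rows <- do.call(rbind, rows)
  if (any(rows$band_low >= 85) && age < 85) {
    message("projection extends past the last closed band; ",
            "open (85+) band rates used")
  }
  contrib <- numeric(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    a <- rows$total_hazard[k]
    contrib[k] <- if (a > 0) {
      (rr * rows$h1[k] / a) * surv * (1 - exp(-rows$width[k] * a))
    } else 0
    surv <- surv * exp(-rows$width[k] * a)
  }
  rows$contribution <- contrib
  structure(list(pi = sum(contrib), rr = rr, ar = ar, horizon = horizon,
                 sex = sex, region = region, age = age, bands = rows),
            class = "absolute_risk")
}

#' @export
print.absolute_risk <- function(x, ...) {
  cat(sprintf(
    "%d-year absolute melanoma risk: %.2f%%  (%s, age %g, %s; RR = %.2f, AR = %.2f)\n",
    x$horizon, 100 * x$pi, x$sex, x$age, x$region, x$rr, x$ar))
  invisible(x)
}

#' Grid of absolute risks over profiles, ages and regions
#'
#' Evaluates \code{\link{absolute_risk}} over a grid, one row per
#' combination, mirroring the published risk tables (percent, 2 dp when
#' printed). Each grid row must carry \code{sex}, \code{age}, \code{region}
#' and either an \code{rr} column or the covariate columns for the matching
#' parameter set.
#'
#' @param rates a \code{rate_table}.
#' @param grid data frame of evaluation points.
#' @param params_female,params_male \code{model_params} used for rows of
#'   each sex (needed for AR, and for RR when the grid has no \code{rr}
#'   column).
#' @return the grid with appended \code{rr_used}, \code{risk} (probability)
#'   and \code{risk_pct} columns.
#' @export
risk_table <- function(rates, grid, params_female = NULL,
                       params_male = NULL) {
  grid <- as.data.frame(grid)
  if (!nrow(grid)) {
    grid$rr_used <- numeric(0)
    grid$risk <- numeric(0)
    grid$risk_pct <- numeric(0)
    return(grid)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, , drop = FALSE]
    params <- if (row$sex == "female") params_female else params_male
    rr <- if ("rr" %in% names(row) && !is.na(row$rr)) row$rr else NULL
    prof <- if (is.null(rr)) as.list(row[setdiff(names(row),
                                                 c("sex", "age", "region",
                                                   "rr"))])
            else NULL
    absolute_risk(rates, row$sex, row$region, row$age, params = params,
                  profile = prof, rr = rr)
  })
  grid$rr_used <- vapply(res, `[[`, numeric(1), "rr")
  grid$risk <- vapply(res, `[[`, numeric(1), "pi")
  grid$risk_pct <- round(100 * grid$risk, 2)
  grid
}
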