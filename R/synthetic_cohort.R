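#' Default simulation configuration for a synthetic case-control cohort
#'
#' Builds the configuration describing the population a synthetic
#' case-control study is drawn from: per-variable level prevalences (taken
#' from the observed control margins of the source study), generating odds
#' ratios (the published sex-specific model estimates; candidates outside
#' the final model default to OR 1), the men's large-mole count distribution,
#' the disease intercept, and arm sizes with frequency matching of controls
#' to cases on age group and region.
#'
#' The disease mechanism is logistic:
#' \eqn{\mathrm{logit}\,P(D=1\mid x) = \alpha + \sum_v \log OR_v(x_v)}.
#' The default intercept puts the marginal disease probability near 1-2%,
#' the rare-disease regime in which odds ratios approximate relative risks.
#'
#' @param sex \code{"female"} or \code{"male"}.
#' @param n_cases,n_controls arm sizes; defaults are the source study's
#'   (182/139 women, 186/131 men).
#' @param intercept baseline log-odds of disease for an all-reference
#'   profile.
#' @param mole_mean mean of the (truncated) Poisson large-mole count for
#'   men.
#' @return a \code{sim_config} list.
#' @export
default_sim_config <- function(sex = c("female", "male"),
                               n_cases = NULL, n_controls = NULL,
                               intercept = -6.2, mole_mean = 0.6) {
  sex <- match.arg(sex)
  if (sex == "female") {
    vars <- list(
      SKINCOLOUR = list(type = "categorical",
                        levels = c("olive", "medium", "fair"),
                        prevalences = c(0.16, 0.38, 0.46),
                        odds_ratios = c(1, 2.94, 4.50)),
      MOLES_RARM = list(type = "categorical",
                        levels = c("0", "1", "2", "3+"),
                        prevalences = c(0.69, 0.17, 0.08, 0.06),
                        odds_ratios = c(1, 1.34, 2.59, 4.28)),
      # Only the "yes" margin is observed (40%); the remainder is split
      # between "no" and a small "don't know" mass.
      FAMHXMOLES = list(type = "categorical",
                        levels = c("don't know", "no", "yes"),
                        prevalences = c(0.05, 0.55, 0.40),
                        odds_ratios = c(1, 1.09, 2.62)),
      NMSC = list(type = "categorical", levels = c("no", "yes"),
                  prevalences = c(0.96, 0.04),
                  odds_ratios = c(1, 3.75)),
      SUNBURN = list(type = "categorical", levels = c("no", "yes"),
                     prevalences = c(0.49, 0.51),
                     odds_ratios = c(1, 1)),
      FRECKLING = list(type = "categorical",
                       levels = c("none", "few", "moderate", "many"),
                       prevalences = c(0.55, 0.32, 0.08, 0.05),
                       odds_ratios = c(1, 1, 1, 1))
    )
    if (is.null(n_cases)) n_cases <- 182L
    if (is.null(n_controls)) n_controls <- 139L
  } else {
    vars <- list(
      OCC18 = list(type = "categorical",
                   levels = c("indoor", "indoor and outdoor", "outdoor"),
                   prevalences = c(0.34, 0.39, 0.27),
                   odds_ratios = c(1, 1.55, 1.94)),
      MOLES_RARM = list(type = "count", mean = mole_mean, max = 20L,
                        per_unit_odds_ratio = 1.15),
      BIRTHPLACE = list(type = "categorical",
                        levels = c("outside NZ", "in NZ"),
                        prevalences = c(0.18, 0.82),
                        odds_ratios = c(1, 2.21)),
      NMSC = list(type = "categorical", levels = c("no", "yes"),
                  prevalences = c(0.96, 0.04),
                  odds_ratios = c(1, 3.10))
    )
    if (is.null(n_cases)) n_cases <- 186L
    if (is.null(n_controls)) n_controls <- 131L
  }
  cfg <- list(
    sex = sex,
    variables = vars,
    # ages drawn by 5-year band with a gently declining adult pyramid
    age_bands = data.frame(
      low = seq(20, 75, 5), high = seq(24, 79, 5),
      weight = c(10, 10, 10, 10, 10, 9, 9, 8, 7, 6, 6, 5)),
    region_prevalences = c(North = 0.35, Midland = 0.25,
                           Central = 0.20, South = 0.20),
    # OR for the over-50 age group: published male estimate; inert in the
    # women's final model
    age_over50_or = if (sex == "male") 2.59 else 1,
    intercept = intercept,
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    match_vars = c("age_group", "region")
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (nm in names(cfg$variables)) {
    v <- cfg$variables[[nm]]
    if (v$type == "categorical") {
      if (abs(sum(v$prevalences) - 1) > 1e-6) {
        stop("prevalences for ", nm, " must sum to 1 (got ",
             sum(v$prevalences), ")", call. = FALSE)
      }
      if (any(v$odds_ratios <= 0)) {
        stop("odds ratios for ", nm, " must be > 0", call. = FALSE)
      }
      if (length(v$prevalences) != length(v$levels) ||
          length(v$odds_ratios) != length(v$levels)) {
        stop("levels, prevalences and odds ratios for ", nm,
             " must have equal length", call. = FALSE)
      }
    }
  }
  if (abs(sum(cfg$region_prevalences) - 1) > 1e-6) {
    stop("region prevalences must sum to 1", call. = FALSE)
  }
  if (cfg$n_cases < 0 || cfg$n_controls < 0) {
    stop("n_cases and n_controls must be >= 0", call. = FALSE)
  }
  cfg
}

#' Generate a synthetic source population
#'
#' Draws \code{n} individuals with covariates sampled independently per
#' variable from the configured prevalences (age band and region from their
#' own margins, exact age uniform within band, the dichotomous age group
#' derived at 50) and assigns disease status from the logistic mechanism
#' \eqn{\mathrm{logit}\,P = \alpha + \sum \log OR}. Fully reproducible given
#' the seed.
#'
#' @param config a \code{sim_config}.
#' @param n number of individuals.
#' @param seed integer RNG seed.
#' @return data frame with \code{id, sex, status, age, age_group, AGE,
#'   region} and one column per configured covariate; the seed is stored in
#'   \code{attr(, "seed")}.
#' @export
generate_population <- function(config, n, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  validate_sim_config(config)
  set.seed(seed)
  if (n == 0) {
    out <- data.frame(id = integer(0), sex = character(0),
                      status = integer(0), age = numeric(0),
                      age_group = character(0), AGE = character(0),
                      region = character(0))
    for (nm in names(config$variables)) out[[nm]] <- character(0)
    attr(out, "seed") <- seed
    return(out)
  }
  ab <- config$age_bands
  band_idx <- sample.int(nrow(ab), n, replace = TRUE,
                         prob = ab$weight / sum(ab$weight))
  age <- ab$low[band_idx] + stats::runif(n) * 5
  age_group <- sprintf("%d-%d", ab$low[band_idx], ab$high[band_idx])
  region <- sample(names(config$region_prevalences), n, replace = TRUE,
                   prob = config$region_prevalences)
  age50 <- ifelse(age <= 50, "<=50", ">50")
  logit <- rep(config$intercept, n)
  logit <- logit + ifelse(age50 == ">50", log(config$age_over50_or), 0)
  out <- data.frame(id = seq_len(n), sex = config$sex, status = NA_integer_,
                    age = age, age_group = age_group, AGE = age50,
                    region = region, stringsAsFactors = FALSE)
  for (nm in names(config$variables)) {
    v <- config$variables[[nm]]
    if (v$type == "categorical") {
      val <- sample(v$levels, n, replace = TRUE, prob = v$prevalences)
      logit <- logit + log(v$odds_ratios)[match(val, v$levels)]
    } else {
      val <- pmin(stats::rpois(n, v$mean), v$max)
      logit <- logit + val * log(v$per_unit_odds_ratio)
    }
    out[[nm]] <- val
  }
  out$status <- stats::rbinom(n, 1L, stats::plogis(logit))
  attr(out, "seed") <- seed
  out
}

# Largest-remainder apportionment of `total` to `props`; RNG breaks
# remainder ties.
largest_remainder <- function(props, total) {
  raw <- props * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    frac <- raw - base
    ord <- order(frac + stats::runif(length(frac)) * 1e-9,
                 decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

#' Sample a frequency-matched case-control study from a population
#'
#' Takes all requested cases at random from the diseased, then samples
#' controls from the disease-free so the controls' joint distribution over
#' the matching factors (age group and region by default) matches the
#' sampled cases' distribution, with largest-remainder rounding of cell
#' targets. With \code{matched = FALSE} controls are a simple random sample.
#'
#' @param population output of \code{\link{generate_population}}.
#' @param n_cases,n_controls arm sizes requested.
#' @param match_vars columns to frequency-match on.
#' @param matched logical; disable for unmatched sampling.
#' @param seed integer RNG seed.
#' @return data frame of \code{n_cases + n_controls} records.
#' @export
sample_case_control <- function(population, n_cases, n_controls,
                                match_vars = c("age_group", "region"),
                                matched = TRUE, seed = 1L) {
  set.seed(seed)
  cases_pool <- population[population$status == 1L, ]
  ctrl_pool <- population[population$status == 0L, ]
  if (nrow(cases_pool) < n_cases) {
    stop("population holds only ", nrow(cases_pool), " cases; ", n_cases,
         " requested", call. = FALSE)
  }
  cases <- cases_pool[sample.int(nrow(cases_pool), n_cases), ]
  if (n_controls == 0) {
    out <- cases
  } else if (!matched) {
    if (nrow(ctrl_pool) < n_controls) {
      stop("not enough disease-free records for ", n_controls, " controls",
           call. = FALSE)
    }
    out <- rbind(cases, ctrl_pool[sample.int(nrow(ctrl_pool), n_controls), ])
  } else {
    cell <- function(d) do.call(paste, c(d[match_vars], sep = "|"))
    case_cells <- table(cell(cases))
    targets <- largest_remainder(as.numeric(case_cells) / n_cases,
                                 n_controls)
    names(targets) <- names(case_cells)
    ctrl_cell <- cell(ctrl_pool)
    picks <- lapply(names(targets), function(cl) {
      need <- targets[[cl]]
      if (need == 0) return(integer(0))
      avail <- which(ctrl_cell == cl)
      if (length(avail) < need) {
        stop("matching cell '", cl, "' has only ", length(avail),
             " controls available; ", need, " needed", call. = FALSE)
      }
      avail[sample.int(length(avail), need)]
    })
    out <- rbind(cases, ctrl_pool[unlist(picks), ])
  }
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "matched") <- matched && n_controls > 0
  out
}

#' Generate a complete synthetic case-control dataset
#'
#' Convenience wrapper: simulates a source population large enough to supply
#' the requested arms, then draws the frequency-matched case-control sample.
#'
#' @param config a \code{sim_config}.
#' @param seed integer RNG seed.
#' @param pop_size source population size (default scales with the arms so
#'   each matching cell is well populated).
#' @return a case-control data frame (see
#'   \code{\link{sample_case_control}}).
#' @export
simulate_case_control <- function(config, seed = 1L, pop_size = NULL) {
  n_arm <- config$n_cases + config$n_controls
  if (n_arm == 0) return(generate_population(config, 0L, seed))
  if (is.null(pop_size)) {
    pop_size <- max(50000L, 400L * config$n_cases)
  }
  pop <- generate_population(config, pop_size, seed)
  sample_case_control(pop, config$n_cases, config$n_controls,
                      match_vars = config$match_vars,
                      seed = seed + 1L)
}

#' Inject and audit missingness
#'
#' Sets a fixed fraction of entries of the named columns to \code{NA},
#' completely at random; \code{audit_completeness} recovers the per-column
#' missing fraction exactly.
#'
#' @param data a data frame.
#' @param vars columns to affect.
#' @param fraction fraction of entries per column to blank (the count is
#'   rounded to the nearest whole number of cells).
#' @param seed integer RNG seed.
#' @export
inject_missingness <- function(data, vars, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed)
  for (v in vars) {
    k <- round(fraction * nrow(data))
    if (k > 0) data[[v]][sample.int(nrow(data), k)] <- NA
  }
  data
}

#' @rdname inject_missingness
#' @export
audit_completeness <- function(data, vars = names(data)) {
  vapply(data[vars], function(x) mean(is.na(x)), numeric(1))
}
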