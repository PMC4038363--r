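#' melrisk: individual 5-year absolute risk of cutaneous melanoma
#'
#' Tools for projecting an individual's 5-year absolute risk of a first
#' cutaneous melanoma in the fair-skinned New Zealand population. The
#' pipeline has three stages: sex-specific logistic models estimated from a
#' population-based case-control study supply per-factor odds ratios, which
#' for a rare disease act as relative risks; the Bruzzi case-based estimator
#' converts the fitted relative risks into the attributable risk (AR) of the
#' modelled factors; and a piecewise-constant two-cause hazard model combines
#' the AR-discounted baseline incidence with competing non-melanoma mortality
#' to give the absolute probability of melanoma over a projection horizon.
#'
#' The package ships the regional age/sex rate tables and the published
#' odds-ratio parameter sets, a seedable synthetic case-control generator so
#' the whole pipeline can be exercised without the original study data, and
#' internal-validation statistics (C-statistic, Hosmer-Lemeshow,
#' classification metrics, linktest).
#'
#' @keywords internal
"_PACKAGE"

REGIONS <- c("North", "Midland", "Central", "South")

# District health boards collated into four latitude groups
.dhb_regions <- c(
  "Northland" = "North", "Waitemata" = "North", "Auckland" = "North",
  "Counties Manukau" = "North",
  "Waikato" = "Midland", "Lakes" = "Midland", "Bay of Plenty" = "Midland",
  "Tairawiti" = "Midland", "Hawke's Bay" = "Midland", "Taranaki" = "Midland",
  "Whanganui" = "Midland",
  "Mid Central" = "Central", "Capital and Coast" = "Central",
  "Hutt" = "Central", "Wairarapa" = "Central", "Nelson" = "Central",
  "Marlborough" = "Central",
  "West Coast" = "South", "Canterbury" = "South",
  "South Canterbury" = "South", "Otago" = "South", "Southland" = "South"
)

#' Map a district health board to its latitude region group
#'
#' The four groups (North, Midland, Central, South) band New Zealand's 22
#' district health boards by latitude; regional melanoma incidence is
#' tabulated at this resolution.
#'
#' @param name district health board name (e.g. \code{"Otago"}).
#' @return one of \code{"North"}, \code{"Midland"}, \code{"Central"},
#'   \code{"South"}.
#' @export
#' @examples
#' region_from_dhb("Otago")
region_from_dhb <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% names(.dhb_regions)) {
    stop("unknown district health board '", name, "'; valid names: ",
         paste(names(.dhb_regions), collapse = ", "), call. = FALSE)
  }
  unname(.dhb_regions[[name]])
}

#' Load a regional incidence/mortality rate table
#'
#' Reads a CSV of average annual melanoma incidence and non-melanoma
#' mortality rates per 100,000 person-years, by sex, region and 5-year age
#' band (20-24 through 80-84, plus an open 85+ band), and validates it:
#' every (sex, region, band) combination must be present, bands must be
#' contiguous and non-overlapping from age 20, rates must be non-negative,
#' and mortality (which is national) must be identical across regions within
#' each sex/band.
#'
#' @param source path to a CSV with columns
#'   \code{sex, region, age_low, age_high, incidence_per_100k,
#'   mortality_per_100k}; the open band has \code{age_high} empty (or a
#'   sentinel of 120). Defaults to the packaged 1996-2006 New Zealand table.
#' @return a \code{rate_table}: a data frame of the validated rows (rates
#'   kept per 100,000/year exactly as printed).
#' @export
load_rate_table <- function(source = nz_rates_path()) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  required <- c("sex", "region", "age_low", "age_high",
                "incidence_per_100k", "mortality_per_100k")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("rate table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$age_high[df$age_high >= 120] <- NA_real_
  validate_rate_table(df)
  class(df) <- c("rate_table", "data.frame")
  df
}

#' @rdname load_rate_table
#' @export
nz_rates_path <- function() {
  system.file("extdata", "nz_rates_1996_2006.csv", package = "melrisk",
              mustWork = TRUE)
}

validate_rate_table <- function(df) {
  bad <- which(df$incidence_per_100k < 0 | df$mortality_per_100k < 0)
  if (length(bad)) {
    stop("negative rate at (", df$sex[bad[1]], ", ", df$region[bad[1]],
         ", ", df$age_low[bad[1]], "-", df$age_high[bad[1]], ")",
         call. = FALSE)
  }
  for (sx in c("female", "male")) {
    for (rg in REGIONS) {
      sub <- df[df$sex == sx & df$region == rg, ]
      if (!nrow(sub)) {
        stop("missing rate rows for (", sx, ", ", rg, ")", call. = FALSE)
      }
      sub <- sub[order(sub$age_low), ]
      lo <- sub$age_low
      hi <- sub$age_high
      if (lo[1] != 20) {
        stop("bands for (", sx, ", ", rg, ") must start at age 20",
             call. = FALSE)
      }
      if (sum(is.na(hi)) != 1L || !is.na(hi[length(hi)])) {
        stop("(", sx, ", ", rg, ") must have exactly one open terminal band",
             call. = FALSE)
      }
      closed <- seq_len(length(lo) - 1L)
      gaps <- which(lo[closed + 1L] != hi[closed] + 1L)
      if (length(gaps)) {
        g <- gaps[1]
        stop("bands for (", sx, ", ", rg, ") are not contiguous around ",
             "age ", hi[g] + 1L, ": band ", lo[g], "-", hi[g],
             " is followed by ", lo[g + 1L], call. = FALSE)
      }
      if (any(hi[closed] < lo[closed])) {
        stop("band with age_high < age_low for (", sx, ", ", rg, ")",
             call. = FALSE)
      }
    }
    # mortality is national within sex/band
    sub <- df[df$sex == sx, ]
    spread <- tapply(sub$mortality_per_100k, sub$age_low,
                     function(v) diff(range(v)))
    if (any(spread > 1e-9)) {
      band <- names(spread)[which(spread > 1e-9)[1]]
      stop("mortality differs across regions for (", sx, ", band starting ",
           band, ")", call. = FALSE)
    }
  }
  invisible(df)
}

#' Write a rate table back to CSV
#'
#' Inverse of \code{\link{load_rate_table}}: writing then reloading
#' reproduces the table cell for cell.
#'
#' @param table a \code{rate_table}.
#' @param path output CSV path.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "rate_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.rate_table <- function(x, ...) {
  cat("Regional melanoma incidence / non-melanoma mortality rate table\n")
  cat("  ", nrow(x), "rows;", length(unique(x$age_low)),
      "age bands from 20; rates per 100,000 person-years\n")
  invisible(x)
}

#' Look up per-person-year hazards for an exact age
#'
#' Finds the age band containing \code{age} and returns the melanoma
#' incidence and non-melanoma mortality hazards converted from per-100,000
#' rates to per-person-year proportions. Ages at or beyond the open band's
#' start use the open (85+) band.
#'
#' @param table a \code{rate_table}.
#' @param sex \code{"female"} or \code{"male"}.
#' @param region one of North, Midland, Central, South.
#' @param age exact age in years, at least 20 (the model's support).
#' @return list with \code{incidence} and \code{mortality} hazards
#'   (per person-year) plus the band bounds used.
#' @export
#' @examples
#' rt <- load_rate_table()
#' lookup_rates(rt, "female", "Midland", 82)
lookup_rates <- function(table, sex, region, age) {
  stopifnot(inherits(table, "rate_table"))
  sex <- match.arg(sex, c("female", "male"))
  region <- match.arg(region, REGIONS)
  if (age < 20) {
    stop("age ", age, " is below the supported range (20+)", call. = FALSE)
  }
  sub <- table[table$sex == sex & table$region == region, ]
  hi <- ifelse(is.na(sub$age_high), Inf, sub$age_high)
  idx <- which(age >= sub$age_low & age < hi + 1)
  if (!length(idx)) stop("no band contains age ", age, call. = FALSE)
  row <- sub[idx[1], ]
  list(incidence = row$incidence_per_100k / 1e5,
       mortality = row$mortality_per_100k / 1e5,
       age_low = row$age_low, age_high = row$age_high)
}

#' Load a sex-specific model parameter set
#'
#' Reads a JSON document holding one sex's fitted odds ratios (per level for
#' categorical variables, per unit for count variables), reference levels,
#' and the attributable risk, and validates it: every odds ratio positive,
#' exactly one reference level with OR 1 per categorical variable, and
#' attributable risk in [0, 1).
#'
#' @param source path to a parameter JSON, or \code{"female"} / \code{"male"}
#'   to load the packaged published parameter set.
#' @return a \code{model_params} object.
#' @export
#' @examples
#' p <- load_model_parameters("female")
#' p$attributable_risk
load_model_parameters <- function(source) {
  if (source %in% c("female", "women")) {
    source <- system.file("extdata", "params_women.json",
                          package = "melrisk", mustWork = TRUE)
  } else if (source %in% c("male", "men")) {
    source <- system.file("extdata", "params_men.json",
                          package = "melrisk", mustWork = TRUE)
  }
  p <- jsonlite::read_json(source, simplifyVector = FALSE)
  if (is.null(p$sex) || is.null(p$variables) || is.null(p$attributable_risk)) {
    stop("parameter file must provide sex, variables and attributable_risk",
         call. = FALSE)
  }
  p$attributable_risk <- as.numeric(p$attributable_risk)
  if (p$attributable_risk < 0 || p$attributable_risk >= 1) {
    stop("attributable_risk must lie in [0, 1)", call. = FALSE)
  }
  p$variables <- lapply(p$variables, function(v) {
    v$type <- match.arg(v$type, c("categorical", "count"))
    if (v$type == "categorical") {
      v$levels <- unlist(v$levels)
      v$odds_ratios <- unlist(v$odds_ratios)
      if (!setequal(names(v$odds_ratios), v$levels)) {
        stop("variable ", v$name, ": odds ratios must cover exactly the ",
             "declared levels", call. = FALSE)
      }
      v$odds_ratios <- v$odds_ratios[v$levels]
      if (any(v$odds_ratios <= 0)) {
        stop("variable ", v$name, ": all odds ratios must be > 0",
             call. = FALSE)
      }
      if (!v$reference %in% v$levels ||
          abs(v$odds_ratios[[v$reference]] - 1) > 1e-12) {
        stop("variable ", v$name, ": reference level must be a declared ",
             "level with odds ratio 1", call. = FALSE)
      }
      refs <- sum(abs(v$odds_ratios - 1) < 1e-12 & v$levels == v$reference)
      if (refs != 1L) {
        stop("variable ", v$name, ": exactly one reference level required",
             call. = FALSE)
      }
    } else {
      v$per_unit_odds_ratio <- as.numeric(v$per_unit_odds_ratio)
      if (!is.finite(v$per_unit_odds_ratio) || v$per_unit_odds_ratio <= 0) {
        stop("variable ", v$name, ": per-unit odds ratio must be > 0",
             call. = FALSE)
      }
    }
    v
  })
  names(p$variables) <- vapply(p$variables, `[[`, "", "name")
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Melanoma risk model parameters (", x$sex, ")\n", sep = "")
  cat("  attributable risk:", x$attributable_risk, "\n")
  for (v in x$variables) {
    if (v$type == "categorical") {
      cat("  ", v$name, ": ",
          paste(sprintf("%s=%.2f", v$levels, v$odds_ratios), collapse = ", "),
          "\n", sep = "")
    } else {
      cat("  ", v$name, ": per-unit OR ", v$per_unit_odds_ratio, "\n",
          sep = "")
    }
  }
  invisible(x)
}
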