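#' Pearson chi-square test of independence
#'
#' The screening statistic used for categorical candidate variables:
#' Pearson's chi-square on the level-by-status contingency table, without
#' continuity correction, with \eqn{(r-1)(c-1)} degrees of freedom.
#'
#' @param tab matrix of non-negative counts, at least 2x2.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
#' @examples
#' chi_square_test(rbind(controls = c(57, 82), cases = c(93, 89)))
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("table must have at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square statistic undefined: zero row or column margin",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

# Which variables are count-valued (entered linearly) rather than
# categorical, per sex. Mole count on the right arm is continuous for men
# but categorical (0/1/2/3+) for women.
#' Default variable typing for each sex-specific model
#'
#' @param sex \code{"female"} or \code{"male"}.
#' @return named character vector mapping candidate variable names to
#'   \code{"categorical"} or \code{"count"}.
#' @export
default_variable_types <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female") {
    c(AGE = "categorical", SUNBURN = "categorical",
      HAIRCOLOUR = "categorical", EYECOLOUR = "categorical",
      SKINCOLOUR = "categorical", FRECKLING = "categorical",
      MOLES_RARM = "categorical", FAMHXMOLES = "categorical",
      NMSC = "categorical")
  } else {
    c(AGE = "categorical", OCC18 = "categorical", OCC_GT18 = "categorical",
      EYECOLOUR = "categorical", SKINCOLOUR = "categorical",
      MOLES_RARM = "count", BIRTHPLACE = "categorical",
      NMSC = "categorical")
  }
}

variable_type <- function(data, var, types) {
  if (!is.null(types) && var %in% names(types)) return(types[[var]])
  if (is.numeric(data[[var]])) "count" else "categorical"
}

#' Univariate screening of candidate variables
#'
#' Tests each candidate's association with case-control status:
#' categorical variables by Pearson chi-square (no continuity correction),
#' count variables by the Wald test on the per-unit coefficient of a
#' univariate logistic fit. Variables with p below the screening threshold
#' are flagged for consideration in the multivariable model.
#'
#' @param data data frame with a binary \code{status} column and the
#'   candidates.
#' @param vars candidate variable names.
#' @param threshold retention threshold on p (default 0.25, a deliberately
#'   permissive screen).
#' @param types optional named vector typing variables as
#'   \code{"categorical"}/\code{"count"}; numeric columns default to count.
#' @return a \code{screening_result} data frame: variable, test, statistic,
#'   df, p, odds ratio (count variables), retained flag.
#' @export
univariate_screen <- function(data, vars, threshold = 0.25, types = NULL) {
  absent <- setdiff(vars, names(data))
  if (length(absent)) {
    stop("variable(s) absent from dataset: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(vars, function(v) {
    keep <- !is.na(data[[v]]) & !is.na(data$status)
    if (variable_type(data, v, types) == "count") {
      fit <- stats::glm(status ~ x, family = stats::binomial(),
                        data = data.frame(status = data$status[keep],
                                          x = as.numeric(data[[v]][keep])))
      s <- summary(fit)$coefficients
      z <- s["x", "z value"]
      data.frame(variable = v, test = "wald_logistic", statistic = z^2,
                 df = 1, p = s["x", "Pr(>|z|)"],
                 odds_ratio = exp(s["x", "Estimate"]))
    } else {
      ct <- chi_square_test(table(data[[v]][keep], data$status[keep]))
      data.frame(variable = v, test = "chi_square",
                 statistic = ct$statistic, df = ct$df, p = ct$p,
                 odds_ratio = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  out$retained <- out$p < threshold
  rownames(out) <- NULL
  class(out) <- c("screening_result", "data.frame")
  out
}

# Coerce covariates to factors with declared reference levels; count
# variables stay numeric.
prepare_model_frame <- function(data, vars, types = NULL, refs = NULL) {
  mf <- data.frame(status = data$status)
  for (v in vars) {
    x <- data[[v]]
    if (variable_type(data, v, types) == "count") {
      mf[[v]] <- as.numeric(x)
    } else {
      x <- factor(x)
      ref <- refs[[v]]
      if (!is.null(ref) && ref %in% levels(x)) x <- stats::relevel(x, ref)
      mf[[v]] <- x
    }
  }
  mf[stats::complete.cases(mf), , drop = FALSE]
}

#' Fit a multivariable logistic model for case-control status
#'
#' Maximum-likelihood logistic regression of status on the named variables,
#' with dummy coding of categorical variables against their reference
#' levels and count variables entered linearly. Complete-case analysis; no
#' imputation.
#'
#' @param data data frame with \code{status} and the covariates.
#' @param vars variable names to include.
#' @param types optional variable typing (see
#'   \code{\link{default_variable_types}}).
#' @param refs optional named list of reference levels (default: first
#'   factor level).
#' @return a \code{cc_fit}: the glm fit plus coefficient table (reference
#'   levels carried as exact zeros), covariance, log-likelihood, AIC, n, and
#'   a convergence flag (separation or non-convergence is flagged, not
#'   fatal).
#' @export
fit_logistic <- function(data, vars, types = NULL, refs = NULL) {
  if (!"status" %in% names(data)) {
    stop("dataset has no status column", call. = FALSE)
  }
  mf <- prepare_model_frame(data, vars, types, refs)
  if (length(unique(mf$status)) < 2) {
    stop("outcome must contain both cases and controls", call. = FALSE)
  }
  form <- stats::as.formula(paste("status ~", paste(vars, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = mf)
  separated <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  coefs <- lapply(vars, function(v) {
    if (is.factor(mf[[v]])) {
      lv <- levels(mf[[v]])
      beta <- c(0, stats::coef(fit)[paste0(v, lv[-1])])
      data.frame(variable = v, level = lv, beta = unname(beta),
                 odds_ratio = exp(unname(beta)))
    } else {
      b <- stats::coef(fit)[[v]]
      data.frame(variable = v, level = "(per unit)", beta = b,
                 odds_ratio = exp(b))
    }
  })
  structure(list(
    glm = fit,
    variables = vars,
    coef_table = do.call(rbind, coefs),
    vcov = stats::vcov(fit),
    logLik = as.numeric(stats::logLik(fit)),
    aic = fit$aic,
    n = nrow(mf),
    converged = fit$converged && !separated,
    types = types, refs = refs
  ), class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("Case-control logistic model (n = ", x$n, ")\n", sep = "")
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  cat("  log-likelihood:", format(x$logLik, digits = 6),
      "  AIC:", format(x$aic, digits = 6), "\n")
  if (!x$converged) cat("  WARNING: fit flagged (non-convergence or separation)\n")
  print(x$coef_table, digits = 3)
  invisible(x)
}

lr_test <- function(fit_full, fit_reduced) {
  stat <- 2 * (fit_full$logLik - fit_reduced$logLik)
  # residual-df difference is robust to rank-deficient columns
  df <- fit_reduced$glm$df.residual - fit_full$glm$df.residual
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Backward selection by likelihood-ratio tests
#'
#' Starting from the full model on all candidates, repeatedly drops the
#' variable whose removal has the largest likelihood-ratio p-value, until
#' every remaining variable's LR p is at or below \code{stay_p}. All fits
#' use the complete-case subset on the full candidate list so nested models
#' share one sample. Each step is recorded in a trace (the AIC of each
#' candidate removal is carried in the trace so non-nested recodings can be
#' compared on AIC).
#'
#' @param data data frame with \code{status} and candidates.
#' @param candidates candidate variable names (non-empty).
#' @param stay_p retention threshold on the LR p-value.
#' @param types,refs see \code{\link{fit_logistic}}.
#' @return list with \code{model} (the final \code{cc_fit}, refitted on its
#'   own complete cases) and \code{trace} (one row per elimination step).
#' @export
backward_select <- function(data, candidates, stay_p = 0.05,
                            types = NULL, refs = NULL) {
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  mf <- prepare_model_frame(data, candidates, types, refs)
  current <- candidates
  trace <- list()
  fit <- fit_logistic(mf, current, types, refs)
  while (length(current) > 1) {
    drops <- lapply(current, function(v) {
      red <- fit_logistic(mf, setdiff(current, v), types, refs)
      lt <- lr_test(fit, red)
      data.frame(variable = v, lr_statistic = lt$statistic, df = lt$df,
                 p = lt$p, aic_without = red$aic)
    })
    drops <- do.call(rbind, drops)
    worst <- which.max(drops$p)
    if (drops$p[worst] <= stay_p) break
    dropped <- drops$variable[worst]
    current <- setdiff(current, dropped)
    fit <- fit_logistic(mf, current, types, refs)
    trace[[length(trace) + 1L]] <-
      cbind(step = length(trace) + 1L, action = "drop",
            drops[worst, , drop = FALSE],
            model_after = paste(current, collapse = "+"))
  }
  # last remaining variable can still be dropped to the null model
  if (length(current) == 1) {
    null_fit <- fit_logistic(cbind(mf, .null = 0), ".null", refs = refs,
                             types = c(.null = "count"))
    lt <- lr_test(fit, null_fit)
    if (lt$p > stay_p) {
      trace[[length(trace) + 1L]] <- data.frame(
        step = length(trace) + 1L, action = "drop", variable = current,
        lr_statistic = lt$statistic, df = lt$df, p = lt$p,
        aic_without = null_fit$aic, model_after = "(intercept only)")
      current <- character(0)
      fit <- null_fit
    }
  }
  if (length(current)) fit <- fit_logistic(data, current, types, refs)
  list(model = fit, selected = current,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), action = character(0),
                    variable = character(0), lr_statistic = numeric(0),
                    df = integer(0), p = numeric(0),
                    aic_without = numeric(0), model_after = character(0)))
}

#' Forward selection by likelihood-ratio tests
#'
#' Mirror of \code{\link{backward_select}} for internal validation: starting
#' from the intercept-only model, repeatedly adds the candidate with the
#' smallest LR p-value while that p-value is below \code{enter_p}.
#'
#' @inheritParams backward_select
#' @param enter_p entry threshold on the LR p-value.
#' @return list with \code{model}, \code{selected} and \code{trace}.
#' @export
forward_select <- function(data, candidates, enter_p = 0.05,
                           types = NULL, refs = NULL) {
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  mf <- prepare_model_frame(data, candidates, types, refs)
  mf$.null <- 0
  types2 <- c(types, .null = "count")
  current <- character(0)
  fit <- fit_logistic(mf, ".null", types = types2)
  trace <- list()
  repeat {
    remaining <- setdiff(candidates, current)
    if (!length(remaining)) break
    adds <- lapply(remaining, function(v) {
      big <- fit_logistic(mf, c(current, v, ".null"), types2, refs)
      lt <- lr_test(big, fit)
      data.frame(variable = v, lr_statistic = lt$statistic, df = lt$df,
                 p = lt$p, aic_with = big$aic)
    })
    adds <- do.call(rbind, adds)
    best <- which.min(adds$p)
    if (adds$p[best] >= enter_p) break
    current <- c(current, adds$variable[best])
    fit <- fit_logistic(mf, c(current, ".null"), types2, refs)
    trace[[length(trace) + 1L]] <-
      cbind(step = length(trace) + 1L, action = "add",
            adds[best, , drop = FALSE],
            model_after = paste(current, collapse = "+"))
  }
  model <- if (length(current)) fit_logistic(data, current, types, refs)
           else fit
  list(model = model, selected = current,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame())
}

#' Bootstrap stability of variable selection
#'
#' Reruns the selection procedure on nonparametric bootstrap resamples
#' (cases and controls resampled within status arm, preserving arm sizes)
#' and reports each candidate's inclusion frequency — the internal-validation
#' check that the chosen model is reproducible under sampling noise.
#'
#' @inheritParams backward_select
#' @param B number of bootstrap resamples.
#' @param direction \code{"backward"} or \code{"forward"}.
#' @param seed integer RNG seed.
#' @return a \code{stability_report} data frame of per-variable inclusion
#'   frequencies; the number of redrawn degenerate resamples is in
#'   \code{attr(, "redraws")}.
#' @export
bootstrap_selection_stability <- function(data, candidates, B = 1000L,
                                          direction = c("backward",
                                                        "forward"),
                                          stay_p = 0.05, types = NULL,
                                          refs = NULL, seed = 1L) {
  stopifnot(B >= 1)
  direction <- match.arg(direction)
  set.seed(seed)
  idx_case <- which(data$status == 1L)
  idx_ctrl <- which(data$status == 0L)
  counts <- stats::setNames(numeric(length(candidates)), candidates)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      take <- c(sample(idx_case, length(idx_case), replace = TRUE),
                sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
      boot <- data[take, ]
      sel <- tryCatch({
        if (direction == "backward") {
          backward_select(boot, candidates, stay_p, types, refs)$selected
        } else {
          forward_select(boot, candidates, stay_p, types, refs)$selected
        }
      }, error = function(e) NULL)
      if (!is.null(sel)) break
      redraws <- redraws + 1L
    }
    counts[sel] <- counts[sel] + 1
  }
  out <- data.frame(variable = candidates,
                    inclusion_frequency = unname(counts / B),
                    B = B, direction = direction)
  attr(out, "redraws") <- redraws
  class(out) <- c("stability_report", "data.frame")
  out
}
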