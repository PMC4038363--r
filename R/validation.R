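#' C-statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen case receives a higher predicted risk
#' than a randomly chosen control, counting ties as one half:
#' \eqn{C = (\mathrm{concordant} + 0.5\,\mathrm{tied}) / (n_1 n_0)}.
#' Computed via the tie-corrected rank-sum identity, which equals
#' exhaustive pair enumeration at any sample size.
#'
#' @param p predicted probabilities (or any risk scores; C is invariant to
#'   strictly monotone transforms).
#' @param y binary outcomes (0/1).
#' @return the C-statistic in [0, 1].
#' @export
c_statistic <- function(p, y) {
  stopifnot(length(p) == length(y))
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(p)           # midranks handle ties as half-concordances
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Rank observations into g near-equal groups by predicted risk, never
# splitting tied predictions across groups.
risk_groups <- function(p, g) {
  ord <- order(p)
  grp <- integer(length(p))
  target <- length(p) / g
  # provisional equal-count grouping, then push ties into one group
  prov <- ceiling(seq_along(ord) / target)
  prov[prov > g] <- g
  vals <- p[ord]
  for (i in seq_along(ord)[-1]) {
    if (vals[i] == vals[i - 1]) prov[i] <- prov[i - 1]
  }
  grp[ord] <- prov
  # renumber in case whole groups were absorbed by ties
  match(grp, sort(unique(grp)))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Ranks observations by predicted risk into \code{g} near-equal groups
#' (tied predictions are kept together, so groups may be unequal), then
#' compares observed and expected events and non-events:
#' \eqn{\sum_g (O_1-E_1)^2/E_1 + (O_0-E_0)^2/E_0}, referred to chi-square
#' with \eqn{g - 2} degrees of freedom. Groups whose expected events or
#' non-events are zero are merged with a neighbour (recorded in the
#' result).
#'
#' @param p predicted probabilities.
#' @param y binary outcomes.
#' @param g number of risk groups (default 10, i.e. deciles of predicted
#'   risk).
#' @return list with \code{statistic}, \code{df}, \code{p}, \code{g_used},
#'   \code{merged} (number of merges), and the group \code{table}.
#' @export
hosmer_lemeshow <- function(p, y, g = 10) {
  stopifnot(length(p) == length(y), length(p) >= g)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  grp <- risk_groups(p, g)
  tab <- data.frame(
    group = sort(unique(grp)),
    n = as.vector(tapply(y, grp, length)),
    observed = as.vector(tapply(y, grp, sum)),
    expected = as.vector(tapply(p, grp, sum)))
  merged <- 0L
  repeat {
    bad <- which(tab$expected < 1e-12 |
                 (tab$n - tab$expected) < 1e-12)
    if (!length(bad) || nrow(tab) <= 2) break
    i <- bad[1]
    j <- if (i == 1) 2L else i - 1L
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, ]
    merged <- merged + 1L
  }
  g_used <- nrow(tab)
  e1 <- tab$expected
  e0 <- tab$n - tab$expected
  stat <- sum((tab$observed - e1)^2 / e1 +
              ((tab$n - tab$observed) - e0)^2 / e0)
  df <- max(g_used - 2, 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       g_used = g_used, merged = merged, table = tab)
}

#' Classification metrics at a probability cutoff
#'
#' Standard 2x2 classification of predicted probabilities against outcomes:
#' sensitivity, specificity and the percentage correctly classified
#' (predicted case when \eqn{p \ge} cutoff).
#'
#' @param p predicted probabilities.
#' @param y binary outcomes.
#' @param cutoff classification threshold in (0, 1); default 0.5.
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{percent_correct} (0-100) and the confusion counts.
#' @export
classification_metrics <- function(p, y, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff < 1, length(p) == length(y))
  y <- as.integer(y)
  pred <- as.integer(p >= cutoff)
  tp <- sum(pred == 1L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       percent_correct = 100 * (tp + tn) / length(y),
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Linktest for model specification
#'
#' Refits the outcome on the model's linear predictor \eqn{\eta} and its
#' square \eqn{\eta^2}; a significant \eqn{\eta^2} coefficient signals that
#' the linear predictor is misspecified (e.g. an omitted nonlinearity).
#'
#' @param fit a \code{cc_fit} from \code{\link{fit_logistic}}.
#' @return list with the \eqn{\eta^2} \code{coefficient}, its Wald
#'   \code{p}, and the auxiliary glm.
#' @export
linktest <- function(fit) {
  stopifnot(inherits(fit, "cc_fit"))
  eta <- stats::predict(fit$glm, type = "link")
  if (stats::sd(eta) < 1e-10) {
    stop("linear predictor is constant; linktest undefined", call. = FALSE)
  }
  y <- fit$glm$y
  aux <- stats::glm(y ~ eta + I(eta^2), family = stats::binomial())
  s <- summary(aux)$coefficients
  if (!"I(eta^2)" %in% rownames(s)) {
    stop("eta and eta^2 are collinear; linktest undefined", call. = FALSE)
  }
  list(coefficient = s["I(eta^2)", "Estimate"],
       p = s["I(eta^2)", "Pr(>|z|)"], fit = aux)
}

#' Observed vs expected risk by decile of predicted risk
#'
#' Splits observations into deciles of predicted risk (ties never split
#' across groups) and reports, per group, the mean predicted probability,
#' the observed event proportion and counts — the table behind the
#' standard calibration plot.
#'
#' @param p predicted probabilities.
#' @param y binary outcomes.
#' @param g number of groups (default 10).
#' @return data frame with \code{group, n, mean_predicted, observed_prop,
#'   observed, expected}.
#' @export
calibration_deciles <- function(p, y, g = 10) {
  stopifnot(length(p) >= g)
  y <- as.integer(y)
  grp <- risk_groups(p, g)
  data.frame(
    group = sort(unique(grp)),
    n = as.vector(tapply(y, grp, length)),
    mean_predicted = as.vector(tapply(p, grp, mean)),
    observed_prop = as.vector(tapply(y, grp, mean)),
    observed = as.vector(tapply(y, grp, sum)),
    expected = as.vector(tapply(p, grp, sum)))
}

#' Full internal-validation report for a fitted risk model
#'
#' Bundles discrimination (C-statistic), calibration (Hosmer-Lemeshow and
#' the observed-vs-expected decile table), classification at a cutoff, and
#' the linktest specification check.
#'
#' @param fit a \code{cc_fit}.
#' @param cutoff classification cutoff (default 0.5).
#' @param g Hosmer-Lemeshow / calibration group count (default 10).
#' @return a \code{validation_report} list.
#' @export
validate_model <- function(fit, cutoff = 0.5, g = 10) {
  p <- stats::predict(fit$glm, type = "response")
  y <- fit$glm$y
  structure(list(
    c_statistic = c_statistic(p, y),
    hosmer_lemeshow = hosmer_lemeshow(p, y, g),
    classification = classification_metrics(p, y, cutoff),
    linktest = linktest(fit),
    calibration = calibration_deciles(p, y, g),
    n = length(y)), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Risk model internal validation (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  C-statistic: %.3f\n", x$c_statistic))
  cat(sprintf("  Hosmer-Lemeshow: chi2 = %.2f on %d df, p = %.3f\n",
              x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$df,
              x$hosmer_lemeshow$p))
  cat(sprintf("  Correctly classified: %.1f%% (sens %.2f, spec %.2f)\n",
              x$classification$percent_correct,
              x$classification$sensitivity, x$classification$specificity))
  cat(sprintf("  Linktest eta^2: coef %.3f, p = %.3f\n",
              x$linktest$coefficient, x$linktest$p))
  invisible(x)
}

#' Calibration plot of observed vs expected risk deciles
#'
#' Observed event proportion against mean predicted probability per decile
#' of predicted risk, circle area proportional to group size, identity line
#' for reference.
#'
#' @param report a \code{validation_report} or the data frame from
#'   \code{\link{calibration_deciles}}.
#' @param ... passed to \code{plot}.
#' @export
plot_calibration <- function(report, ...) {
  tab <- if (inherits(report, "validation_report")) report$calibration
         else report
  lim <- range(0, tab$mean_predicted, tab$observed_prop)
  graphics::plot(tab$mean_predicted, tab$observed_prop, xlim = lim,
                 ylim = lim, cex = 3 * sqrt(tab$n / max(tab$n)),
                 xlab = "Expected (mean predicted) proportion",
                 ylab = "Observed proportion", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(tab)
}
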