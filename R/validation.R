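check_pred_outcome <- function(predicted, outcome, need_both_classes = TRUE) {
  if (length(predicted) != length(outcome))
    stop_input("predicted and outcome must have equal length (%d vs %d)",
               length(predicted), length(outcome))
  if (any(!is.finite(predicted)) || any(predicted < 0) || any(predicted > 1))
    stop_input("predicted values must be probabilities in [0, 1]")
  if (any(!outcome %in% c(0L, 1L)))
    stop_input("outcomes must be binary 0/1")
  if (need_both_classes && (all(outcome == 0) || all(outcome == 1)))
    stop_input("degenerate input: both outcome classes must be present")
  invisible(TRUE)
}

#' ROC curve and AUC
#'
#' The ROC is traced over all distinct score thresholds (plus the endpoints
#' (0,0) and (1,1)); the AUC is the rank (Mann-Whitney) statistic, so tied
#' positive-negative score pairs count one half — identical to the
#' trapezoidal area under the tie-aware ROC.
#'
#' @param predicted Predicted probabilities.
#' @param outcome Binary outcomes (1 = at least one fall).
#' @return List with `roc_points` (data frame `fpr`, `tpr`, monotone from
#'   (0,0) to (1,1)) and `auc`.
#' @export
#' @examples
#' roc_and_auc(c(0.8, 0.6, 0.7, 0.1), c(1, 1, 0, 0))$auc   # 0.75
roc_and_auc <- function(predicted, outcome) {
  check_pred_outcome(predicted, outcome)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  ord <- order(predicted, decreasing = TRUE)
  p <- predicted[ord]; o <- outcome[ord]
  keep <- c(p[-length(p)] != p[-1L], TRUE)   # last index of each tie block
  tpr <- c(0, cumsum(o == 1)[keep] / n1)
  fpr <- c(0, cumsum(o == 0)[keep] / n0)
  r <- rank(predicted, ties.method = "average")
  auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Mid-rank placements (DeLong): per-positive and per-negative empirical
# probabilities of correct ordering against the opposite class.
delong_placements <- function(predicted, outcome) {
  x <- predicted[outcome == 1]; y <- predicted[outcome == 0]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rank(x, ties.method = "average")) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01)
}

#' Confidence interval for the AUC
#'
#' Default: DeLong's closed-form variance from mid-rank placements. With
#' `method = "bootstrap"`, a percentile interval from stratified resampling
#' (positives and negatives resampled separately, preserving both classes),
#' or cluster resampling when `cluster` ids are supplied (repeated
#' observations per subject).
#'
#' @param predicted,outcome As in [roc_and_auc()].
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap (required for that method).
#' @param cluster Optional vector of cluster ids for cluster bootstrap.
#' @return List `ci = c(lower, upper)` (clamped to `[0, 1]`, containing the
#'   point estimate), `auc`, `se` (DeLong only), `method`.
#' @export
auc_confidence_interval <- function(predicted, outcome, level = 0.95,
                                    method = c("delong", "bootstrap"),
                                    n_boot = 2000L, seed = NULL,
                                    cluster = NULL) {
  method <- match.arg(method)
  check_pred_outcome(predicted, outcome)
  auc <- roc_and_auc(predicted, outcome)$auc
  if (method == "delong") {
    pl <- delong_placements(predicted, outcome)
    se <- sqrt(stats::var(pl$v10) / length(pl$v10) +
               stats::var(pl$v01) / length(pl$v01))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(max(0, auc - z * se), min(1, auc + z * se))
    return(list(ci = ci, auc = auc, se = se, method = "delong"))
  }
  if (is.null(seed)) stop_input("bootstrap CI requires an explicit seed")
  boots <- with_seed(seed, {
    if (is.null(cluster)) {
      ip <- which(outcome == 1); im <- which(outcome == 0)
      vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
        roc_and_auc(predicted[idx], outcome[idx])$auc
      }, numeric(1))
    } else {
      ids <- unique(cluster)
      out <- numeric(0)
      while (length(out) < n_boot) {
        pick <- sample(ids, replace = TRUE)
        idx <- unlist(lapply(pick, function(id) which(cluster == id)))
        if (all(outcome[idx] == 0) || all(outcome[idx] == 1)) next
        out <- c(out, roc_and_auc(predicted[idx], outcome[idx])$auc)
      }
      out
    }
  })
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  ci <- c(max(0, min(qs[1], auc)), min(1, max(qs[2], auc)))
  list(ci = ci, auc = auc, method = "bootstrap", n_boot = n_boot, seed = seed)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome.
#'
#' @inheritParams roc_and_auc
#' @return The score in `[0, 1]`.
#' @export
brier_score <- function(predicted, outcome) {
  check_pred_outcome(predicted, outcome, need_both_classes = FALSE)
  mean((predicted - outcome)^2)
}

# Quantile bins over predicted risk; ties at edges fall into the lower bin,
# zero-width bins are merged (with a warning from the caller's context).
risk_bins <- function(predicted, groups) {
  breaks <- stats::quantile(predicted, probs = seq(0, 1, length.out = groups + 1))
  ub <- unique(unname(breaks))
  if (length(ub) < 2L) ub <- c(ub - 1e-12, ub + 1e-12)   # constant predictions
  merged <- length(ub) < groups + 1L
  bins <- cut(predicted, breaks = ub, include.lowest = TRUE, right = TRUE)
  list(bins = bins, merged = merged, n_bins = nlevels(bins))
}

#' Hosmer-Lemeshow calibration test
#'
#' Subjects are ranked into `groups` quantile bins of predicted risk; the
#' statistic is `sum_g (O_g - n_g pbar_g)^2 / (n_g pbar_g (1 - pbar_g))`
#' with `O_g` observed events and `pbar_g` the bin's mean predicted risk,
#' referred to a chi-square upper tail. `df = "g-2"` is the classical
#' convention for a fitted model; for externally specified predictions (no
#' parameters estimated on the data) `df = "g"` is the asymptotically
#' correct choice.
#'
#' @inheritParams roc_and_auc
#' @param groups Number of quantile groups (default 10).
#' @param df `"g-2"` (classical, default) or `"g"`.
#' @param epsilon Guard for bins whose mean predicted risk is exactly 0 or 1.
#' @return List `statistic`, `df`, `p_value`, `n_bins`.
#' @export
hosmer_lemeshow <- function(predicted, outcome, groups = 10L,
                            df = c("g-2", "g"), epsilon = 1e-10) {
  df <- match.arg(df)
  check_pred_outcome(predicted, outcome)
  if (length(predicted) < groups)
    stop_input("need at least %d observations for %d groups", groups, groups)
  rb <- risk_bins(predicted, groups)
  if (rb$merged)
    warning(sprintf("tied predictions: %d quantile bins collapsed to %d",
                    groups, rb$n_bins), call. = FALSE)
  n_g <- tabulate(rb$bins, nbins = rb$n_bins)
  O_g <- tapply(outcome, rb$bins, sum, default = 0)
  pbar <- tapply(predicted, rb$bins, mean, default = 0)
  denom <- n_g * pbar * (1 - pbar)
  if (any(denom <= 0)) {
    warning("bin(s) with degenerate mean predicted risk; contribution guarded by epsilon",
            call. = FALSE)
    denom <- pmax(denom, n_g * epsilon)
  }
  statistic <- sum((O_g - n_g * pbar)^2 / denom)
  dof <- if (df == "g-2") rb$n_bins - 2L else rb$n_bins
  if (dof < 1L) {
    warning("fewer than 3 effective bins; using 1 degree of freedom", call. = FALSE)
    dof <- 1L
  }
  list(statistic = unname(statistic), df = dof,
       p_value = stats::pchisq(statistic, dof, lower.tail = FALSE),
       n_bins = rb$n_bins)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Decile calibration table
#'
#' Per risk-decile: group size, mean predicted risk, observed faller
#' proportion and its Wilson 95\% interval — the numbers behind a
#' calibration plot.
#'
#' @inheritParams hosmer_lemeshow
#' @param level Confidence level for the Wilson intervals.
#' @return Data frame with columns `decile`, `n`, `mean_predicted`,
#'   `observed_proportion`, `ci_lower`, `ci_upper`; the groups partition the
#'   sample.
#' @export
calibration_table <- function(predicted, outcome, groups = 10L, level = 0.95) {
  check_pred_outcome(predicted, outcome)
  rb <- risk_bins(predicted, groups)
  if (rb$merged)
    warning(sprintf("tied predictions: calibration table collapsed to %d group(s)",
                    rb$n_bins), call. = FALSE)
  n_g <- tabulate(rb$bins, nbins = rb$n_bins)
  O_g <- as.numeric(tapply(outcome, rb$bins, sum, default = 0))
  pbar <- as.numeric(tapply(predicted, rb$bins, mean, default = 0))
  cis <- t(mapply(wilson_ci, O_g, n_g, MoreArgs = list(level = level)))
  data.frame(decile = seq_len(rb$n_bins), n = n_g,
             mean_predicted = pbar, observed_proportion = O_g / n_g,
             ci_lower = cis[, 1], ci_upper = cis[, 2])
}

#' Full validation report
#'
#' Bundles the evaluation battery for a set of predictions against observed
#' outcomes: ROC/AUC with confidence interval, Brier score, Hosmer-Lemeshow
#' test, and the decile calibration table.
#'
#' @inheritParams auc_confidence_interval
#' @param groups Quantile groups for calibration (default 10).
#' @param hl_df Degrees-of-freedom convention, see [hosmer_lemeshow()].
#' @return A `validation_report` list.
#' @export
validate_predictions <- function(predicted, outcome, level = 0.95,
                                 method = c("delong", "bootstrap"),
                                 groups = 10L, hl_df = c("g-2", "g"),
                                 n_boot = 2000L, seed = NULL, cluster = NULL) {
  method <- match.arg(method); hl_df <- match.arg(hl_df)
  roc <- roc_and_auc(predicted, outcome)
  ci <- auc_confidence_interval(predicted, outcome, level = level,
                                method = method, n_boot = n_boot,
                                seed = seed, cluster = cluster)
  hl <- hosmer_lemeshow(predicted, outcome, groups = groups, df = hl_df)
  structure(list(n = length(outcome),
                 roc_points = roc$roc_points,
                 auc = roc$auc, auc_ci = ci$ci, ci_method = method,
                 brier = brier_score(predicted, outcome),
                 hl_statistic = hl$statistic, hl_df = hl$df,
                 hl_p = hl$p_value,
                 calibration_table = calibration_table(predicted, outcome,
                                                       groups = groups,
                                                       level = level)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation on n = %d (%.1f%% fallers)\n", x$n,
              100 * mean(x$calibration_table$observed_proportion *
                         x$calibration_table$n) * nrow(x$calibration_table) / x$n))
  cat(sprintf("  AUC   %.3f (%.0f%% CI %.3f-%.3f, %s)\n", x$auc, 95,
              x$auc_ci[1], x$auc_ci[2], x$ci_method))
  cat(sprintf("  Brier %.3f\n", x$brier))
  cat(sprintf("  Hosmer-Lemeshow chi2 = %.2f, df = %d, p = %.3g\n",
              x$hl_statistic, x$hl_df, x$hl_p))
  cat("Calibration by decile:\n")
  print(format(x$calibration_table, digits = 3), row.names = FALSE)
  invisible(x)
}
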