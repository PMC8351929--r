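#' Non-parametric Bland-Altman estimates
#'
#' Bias and 95% limits of agreement for a distribution of method
#' differences, estimated non-parametrically — median for the bias, 2.5th
#' and 97.5th percentiles for the lower and upper limits — the appropriate
#' choice when detection errors are quantised to the mocap frame and far
#' from normal. Percentiles interpolate linearly between order statistics
#' (R quantile type 7); this convention is fixed because limits can shift
#' by up to one sample spacing between conventions. A Kolmogorov-Smirnov
#' normality test (against a normal with the sample's own mean and SD, so
#' strictly a Lilliefors-style test; its p-value is approximate and
#' conservative) is reported alongside, but the non-parametric estimates
#' are always what the report carries.
#'
#' @param errors Numeric vector of differences (predicted minus ground
#'   truth), n >= 3.
#' @return A list: `bias`, `la_lower`, `la_upper`, `n`, `normality_D`,
#'   `normality_p`.
#' @examples
#' bland_altman(c(-2, -1, 0, 1, 2))$bias
#' @export
bland_altman <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) < 3) stopf("need at least 3 errors, got %d",
                                length(errors))
  q <- unname(quantile(errors, c(0.025, 0.975), type = 7))
  ks <- suppressWarnings(ks.test(errors, "pnorm", mean(errors),
                                 if (sd(errors) > 0) sd(errors) else 1))
  list(bias = median(errors), la_lower = q[1], la_upper = q[2],
       n = length(errors), normality_D = unname(ks$statistic),
       normality_p = ks$p.value)
}

#' Root mean squared error
#'
#' @param errors Numeric vector of differences; must be non-empty.
#' @return `sqrt(mean(errors^2))`.
#' @examples
#' rmse(c(3, -4))  # sqrt(12.5)
#' @export
rmse <- function(errors) {
  if (length(errors) < 1) stopf("empty error vector")
  sqrt(mean(as.numeric(errors)^2))
}

#' Pearson correlation with magnitude classification
#'
#' Pearson's r with a two-sided test, classified as trivial (|r| < 0.1),
#' small (0.1 <= |r| < 0.3), moderate (0.3 <= |r| < 0.5) or large
#' (|r| >= 0.5); ordinary least-squares slope, intercept and r-squared are
#' attached for non-trivial correlations only.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return A `correlation_result` list: `r`, `p`, `magnitude`, and (when
#'   `|r| >= 0.1`) `slope`, `intercept`, `r_squared`.
#' @examples
#' correlate_and_classify(1:10, 2 * (1:10) + 1)$magnitude  # "large"
#' @export
correlate_and_classify <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  magnitude <- correlation_magnitude(r)
  out <- list(r = r, p = ct$p.value, magnitude = magnitude,
              slope = NULL, intercept = NULL, r_squared = NULL)
  if (magnitude != "trivial") {
    fit <- lm(y ~ x)
    out$slope <- unname(coef(fit)[2])
    out$intercept <- unname(coef(fit)[1])
    out$r_squared <- r^2
  }
  structure(out, class = "correlation_result")
}

#' Classify a correlation coefficient's magnitude
#'
#' @param r Pearson correlation coefficient.
#' @return `"trivial"` (|r| < 0.1), `"small"` (0.1 <= |r| < 0.3),
#'   `"moderate"` (0.3 <= |r| < 0.5) or `"large"` (|r| >= 0.5); each band
#'   is inclusive on its left edge.
#' @export
correlation_magnitude <- function(r) {
  a <- abs(r)
  if (a < 0.1) "trivial" else if (a < 0.3) "small"
  else if (a < 0.5) "moderate" else "large"
}

#' Masked frame classification accuracy
#'
#' Fraction of real (unmasked) frames whose binarised contact prediction
#' matches the ground-truth label, pooled over all cycles. Padded frames
#' are never counted.
#'
#' @param pred A `predicted_contact` object, or a probability matrix.
#' @param targets 0/1 label matrix aligned with the predictions.
#' @param mask 0/1 matrix of real frames (taken from `pred` when it is a
#'   `predicted_contact`).
#' @param threshold Binarisation threshold (default 0.5).
#' @return Proportion in `[0, 1]`.
#' @export
frame_accuracy <- function(pred, targets, mask = NULL, threshold = 0.5) {
  if (inherits(pred, "predicted_contact")) {
    mask <- pred$mask
    pred <- pred$probabilities
  }
  if (is.null(mask)) mask <- matrix(1, nrow(pred), ncol(pred))
  if (!all(dim(pred) == dim(targets)))
    stopf("prediction (%s) and target (%s) dimensions differ",
          paste(dim(pred), collapse = "x"),
          paste(dim(targets), collapse = "x"))
  masked_accuracy(pred, targets, mask, threshold)
}

#' Full agreement report against force-derived ground truth
#'
#' The package's headline assessment: for each event type (foot-strike,
#' toe-off, contact time), non-parametric Bland-Altman bias and 95% limits
#' of agreement, RMSE, and the normality verdict, from the per-cycle
#' errors in milliseconds (predicted minus ground truth; negative = early
#' detection).
#'
#' @param errors Data frame from [event_errors()].
#' @param frame_accuracy Optional pooled frame accuracy to carry in the
#'   report.
#' @return An `agreement_report` data frame: one row per event type with
#'   `bias_ms`, `la_lower_ms`, `la_upper_ms`, `rmse_ms`, `n`,
#'   `normality_p`.
#' @export
agreement_report <- function(errors, frame_accuracy = NA_real_) {
  cols <- c(foot_strike = "fs_error_ms", toe_off = "to_error_ms",
            contact_time = "ct_error_ms")
  rows <- lapply(names(cols), function(ev) {
    e <- errors[[cols[[ev]]]]
    ba <- bland_altman(e)
    data.frame(event = ev, bias_ms = ba$bias, la_lower_ms = ba$la_lower,
               la_upper_ms = ba$la_upper, rmse_ms = rmse(e), n = ba$n,
               normality_D = ba$normality_D, normality_p = ba$normality_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "frame_accuracy") <- frame_accuracy
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  acc <- attr(x, "frame_accuracy")
  cat("Agreement against force-derived ground truth\n")
  if (!is.na(acc)) cat(sprintf("  frame accuracy: %.2f%%\n", 100 * acc))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s bias %5.1f ms  95%%LA [%6.1f, %6.1f] ms  RMSE %5.2f ms  (n = %d)\n",
                x$event[i], x$bias_ms[i], x$la_lower_ms[i], x$la_upper_ms[i],
                x$rmse_ms[i], x$n[i]))
  invisible(x)
}

#' Bland-Altman plot of event-timing errors
#'
#' Error against the mean of the two methods' event times, with the median
#' bias and the 2.5th/97.5th percentile limits drawn as horizontal lines.
#' Requires ggplot2.
#'
#' @param errors Error vector (ms).
#' @param means Per-cycle mean of predicted and ground-truth event values.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(errors, means, title = "Bland-Altman") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("ggplot2 is required for plotting")
  ba <- bland_altman(errors)
  df <- data.frame(means = means, errors = errors)
  ggplot2::ggplot(df, ggplot2::aes(x = means, y = errors)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$la_lower, ba$la_upper),
                        linetype = 2) +
    ggplot2::labs(title = title, x = "mean of methods (ms)",
                  y = "difference (ms)") +
    ggplot2::theme_minimal()
}
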