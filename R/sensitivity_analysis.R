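#' Band an angle error magnitude
#'
#' The interpretability bands for joint-angle error caused by event-timing
#' error, grounded in the reliability of marker-based kinematics: below 2
#' degrees is acceptable, 2 to 5 degrees is reasonable but requires
#' consideration, above 5 degrees is unacceptable (boundaries: 2 maps to
#' reasonable, 5 maps to reasonable).
#'
#' @param mean_abs_error Non-negative angle error in degrees.
#' @return `"acceptable"`, `"reasonable"` or `"unacceptable"`.
#' @examples
#' classify_band(1.9); classify_band(2); classify_band(5.01)
#' @export
classify_band <- function(mean_abs_error) {
  if (length(mean_abs_error) != 1 || !is.finite(mean_abs_error) ||
      mean_abs_error < 0)
    stopf("mean_abs_error must be a single non-negative number")
  if (mean_abs_error < 2) "acceptable"
  else if (mean_abs_error <= 5) "reasonable"
  else "unacceptable"
}

#' Sensitivity of joint angles to event-timing error
#'
#' For every cycle, joint and event, compares the angle at the
#' ground-truth event frame with the angle at the frames up to
#' `max_offset` either side of it: the error at offset `delta` is
#' `angle(event + delta) - angle(event)`. Errors are aggregated per
#' (joint, event, offset) cell into mean, SD and mean absolute error, and
#' each cell is banded with [classify_band()] on its mean absolute error.
#' Cycles whose shifted frame falls outside the cycle are excluded from
#' that offset and counted.
#'
#' @param angles A list, one element per cycle, each a named list or matrix
#'   of per-frame joint angles in degrees (`hip`, `knee`, `ankle`), or a
#'   `gait_cycle_list` (hip/knee from the auxiliary channels, ankle from
#'   the feature matrix).
#' @param truth_events A `step_events` data frame with one row per cycle
#'   (ground-truth foot-strike and toe-off, 0-based frames).
#' @param max_offset Largest frame shift examined either side (default 5;
#'   at 200 Hz, 5 frames is 25 ms).
#' @param rate Mocap rate, used to report the ms equivalent of each offset.
#' @return A `sensitivity_grid` data frame: joint, event, offset_frames,
#'   offset_ms, mean_error, sd_error, mean_abs_error, band, n, n_excluded.
#' @export
angle_sensitivity <- function(angles, truth_events, max_offset = 5L,
                              rate = NULL) {
  if (inherits(angles[[1]], "gait_cycle")) {
    rate <- rate %||% angles[[1]]$rate
    angles <- lapply(angles, function(cy)
      cbind(hip = cy$aux[, "hip_angle"], knee = cy$aux[, "knee_angle"],
            ankle = cy$features[, "ankle_angle"]))
  }
  if (length(angles) != nrow(truth_events))
    stopf("%d angle cycles vs %d event rows", length(angles),
          nrow(truth_events))
  rate <- rate %||% truth_events$rate[1]
  joints <- colnames(angles[[1]])
  offsets <- setdiff(seq(-max_offset, max_offset), 0L)
  events <- c(foot_strike = "foot_strike_index", toe_off = "toe_off_index")
  grid <- expand.grid(joint = joints, event = names(events),
                      offset_frames = offsets, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    joint <- grid$joint[g]; ev <- grid$event[g]; d <- grid$offset_frames[g]
    errs <- rep(NA_real_, length(angles))
    for (i in seq_along(angles)) {
      a <- angles[[i]][, joint]
      idx <- truth_events[[events[[ev]]]][i] + 1L   # to 1-based
      if (idx + d >= 1 && idx + d <= length(a))
        errs[i] <- a[idx + d] - a[idx]
    }
    excl <- sum(is.na(errs))
    errs <- errs[!is.na(errs)]
    mae <- mean(abs(errs))
    data.frame(joint = joint, event = ev, offset_frames = d,
               offset_ms = d / rate * 1000, mean_error = mean(errs),
               sd_error = if (length(errs) > 1) sd(errs) else 0,
               mean_abs_error = mae, band = classify_band(mae),
               n = length(errs), n_excluded = excl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_grid", "data.frame")
  out
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid: %d joints x %d events x %d offsets>\n",
              length(unique(x$joint)), length(unique(x$event)),
              length(unique(x$offset_frames))))
  worst <- x[x$band == "unacceptable", ]
  if (nrow(worst))
    cat(sprintf("  unacceptable cells: %s\n",
                paste(sprintf("%s@%s%+d", worst$joint, worst$event,
                              worst$offset_frames), collapse = ", ")))
  invisible(x)
}
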