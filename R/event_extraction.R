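#' Step events for one gait cycle
#'
#' Foot-strike and toe-off as 0-based mocap frame indices from cycle start
#' (frame `i` is at time `i / rate`), with times in milliseconds and the
#' contact time between them.
#'
#' @param foot_strike_index,toe_off_index 0-based mocap frame indices,
#'   `foot_strike_index <= toe_off_index`.
#' @param rate Mocap rate in Hz.
#' @param cycle_id Optional identifier.
#' @return A one-row data frame of class `step_events`.
#' @examples
#' step_events(21, 80, rate = 200)
#' @export
step_events <- function(foot_strike_index, toe_off_index, rate,
                        cycle_id = "") {
  if (foot_strike_index > toe_off_index)
    stopf("foot-strike frame %d after toe-off frame %d",
          foot_strike_index, toe_off_index)
  out <- data.frame(cycle_id = cycle_id,
                    foot_strike_index = as.integer(foot_strike_index),
                    toe_off_index = as.integer(toe_off_index),
                    foot_strike_time_ms = foot_strike_index / rate * 1000,
                    toe_off_time_ms = toe_off_index / rate * 1000,
                    contact_time_ms =
                      (toe_off_index - foot_strike_index) / rate * 1000,
                    rate = rate, stringsAsFactors = FALSE)
  class(out) <- c("step_events", "data.frame")
  out
}

# longest run of TRUE in a logical vector; ties -> first. Returns c(start,
# end) 1-based or NULL.
longest_true_run <- function(x) {
  r <- rle(x)
  runs <- which(r$values)
  if (!length(runs)) return(NULL)
  best <- runs[which.max(r$lengths[runs])]
  e <- cumsum(r$lengths)
  c(e[best] - r$lengths[best] + 1L, e[best])
}

#' Extract foot-strike and toe-off from predicted contact probabilities
#'
#' Binarises the per-frame contact probabilities at `threshold` over the
#' unmasked (real) frames, takes the longest contiguous contact run —
#' robust to isolated supra-threshold frames in the swing phase — and
#' reports its first frame as foot-strike and last frame as toe-off,
#' mirroring the force-based "first and last frame of contact" ground
#' truth. Indices are relative to cycle start, i.e. with padding removed.
#'
#' @param prob Numeric vector of per-frame contact probabilities (padded
#'   length), or a matrix row thereof.
#' @param mask 0/1 vector flagging real frames; defaults to all real.
#' @param rate Mocap rate in Hz.
#' @param threshold Decision threshold (default 0.5; a probability exactly
#'   at the threshold counts as contact).
#' @param cycle_id Optional identifier.
#' @return A [step_events()] row.
#' @examples
#' extract_events(c(.1, .2, .9, .8, .9, .1), rate = 200)
#' @export
extract_events <- function(prob, rate, mask = NULL, threshold = 0.5,
                           cycle_id = "") {
  prob <- as.numeric(prob)
  if (is.null(mask)) mask <- rep(1L, length(prob))
  real <- which(mask == 1)
  if (!length(real)) stopf("no unmasked frames")
  p <- prob[real]
  run <- longest_true_run(p >= threshold)
  if (is.null(run))
    stopf("no contact detected in cycle '%s' (max probability %.3f < threshold %g)",
          cycle_id, max(p), threshold)
  step_events(run[1] - 1L, run[2] - 1L, rate, cycle_id = cycle_id)
}

#' Extract events for every cycle of a prediction batch
#'
#' @param pred A `predicted_contact` object from [predict_contact()].
#' @param threshold Decision threshold.
#' @return A `step_events` data frame, one row per cycle.
#' @export
extract_events_batch <- function(pred, threshold = 0.5) {
  stopifnot(inherits(pred, "predicted_contact"))
  out <- do.call(rbind, lapply(seq_len(nrow(pred$probabilities)), function(i)
    extract_events(pred$probabilities[i, ], rate = pred$rate,
                   mask = pred$mask[i, ], threshold = threshold,
                   cycle_id = pred$cycle_ids[i])))
  class(out) <- c("step_events", "data.frame")
  out
}

#' Event-timing errors against ground truth
#'
#' Differences predicted minus force-derived ground truth, in
#' milliseconds, for foot-strike, toe-off and contact time. Positive
#' foot-strike/toe-off error means late detection; positive contact-time
#' error means overestimated contact. By construction the contact-time
#' error equals the toe-off error minus the foot-strike error.
#'
#' @param pred,truth [step_events()] data frames; rows are matched by
#'   `cycle_id` when both carry ids, otherwise by position.
#' @return Data frame with `cycle_id`, `fs_error_ms`, `to_error_ms`,
#'   `ct_error_ms`.
#' @export
event_errors <- function(pred, truth) {
  if (!all(pred$rate == truth$rate[1]) || !all(truth$rate == truth$rate[1]))
    stopf("rate mismatch between predicted and ground-truth events")
  if (all(nzchar(pred$cycle_id)) && all(nzchar(truth$cycle_id))) {
    orphans <- c(setdiff(pred$cycle_id, truth$cycle_id),
                 setdiff(truth$cycle_id, pred$cycle_id))
    if (length(orphans))
      stopf("cycle ids missing from one side: %s",
            paste(orphans, collapse = ", "))
    truth <- truth[match(pred$cycle_id, truth$cycle_id), ]
  } else if (nrow(pred) != nrow(truth)) {
    stopf("cannot match %d predicted rows to %d truth rows without ids",
          nrow(pred), nrow(truth))
  }
  data.frame(cycle_id = pred$cycle_id,
             fs_error_ms = pred$foot_strike_time_ms - truth$foot_strike_time_ms,
             to_error_ms = pred$toe_off_time_ms - truth$toe_off_time_ms,
             ct_error_ms = pred$contact_time_ms - truth$contact_time_ms,
             stringsAsFactors = FALSE)
}
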