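#' A single gait cycle
#'
#' The unit of analysis: one stride from a foot-COM vertical-position apex
#' to the next, bundling the four kinematic model-input channels at mocap
#' rate, the synchronised vertical GRF at force rate, optional contact
#' labels, and metadata.
#'
#' @param features Numeric matrix, samples x 4, columns `tibia_ap_vel`
#'   (m/s), `ankle_angle` (deg), `foot_ap_vel` (m/s), `foot_vert_vel` (m/s)
#'   in that fixed order.
#' @param rate Mocap sampling rate in Hz.
#' @param vgrf Optional [time_series()] of vertical GRF in newtons at the
#'   force rate; its duration must match the features within one mocap
#'   frame.
#' @param aux Optional matrix of auxiliary channels at mocap rate
#'   (`hip_angle`, `knee_angle`, `foot_vert_pos`).
#' @param labels Optional 0/1 integer vector of contact labels at mocap
#'   rate (built by [label_contact()]).
#' @param participant_id,dataset_id,cycle_id Identifiers.
#' @param speed,incline,strike_pattern,foot_strike_angle Cycle conditions.
#' @param truth Optional [synthetic_cycle_truth()] for generated cycles.
#' @param accepted QC verdict (`NA` until [qc_filter()] has run).
#' @return A `gait_cycle` object.
#' @export
gait_cycle <- function(features, rate, vgrf = NULL, aux = NULL, labels = NULL,
                       participant_id = "", dataset_id = "", cycle_id = "",
                       speed = NA_real_, incline = NA_real_,
                       strike_pattern = NA_character_,
                       foot_strike_angle = NA_real_, truth = NULL,
                       accepted = NA) {
  features <- as.matrix(features)
  expected <- c("tibia_ap_vel", "ankle_angle", "foot_ap_vel", "foot_vert_vel")
  if (ncol(features) != 4L)
    stopf("features must have exactly 4 channels, got %d", ncol(features))
  if (is.null(colnames(features))) colnames(features) <- expected
  if (!identical(colnames(features), expected))
    stopf("feature columns must be %s in order", paste(expected, collapse = ", "))
  if (any(!is.finite(features)))
    stopf("cycle '%s': non-finite feature values", cycle_id)
  if (!is.null(vgrf)) {
    stopifnot(inherits(vgrf, "time_series"))
    d_kin <- nrow(features) / rate
    d_frc <- length(vgrf$values) / vgrf$rate
    if (abs(d_kin - d_frc) > 1 / rate + 1e-9)
      stopf("cycle '%s': vGRF duration %.4f s differs from kinematics %.4f s by more than one mocap frame",
            cycle_id, d_frc, d_kin)
  }
  structure(list(features = features, rate = rate, vgrf = vgrf, aux = aux,
                 labels = labels, events = NULL,
                 participant_id = participant_id, dataset_id = dataset_id,
                 cycle_id = cycle_id, speed = speed, incline = incline,
                 strike_pattern = strike_pattern,
                 foot_strike_angle = foot_strike_angle,
                 truth = truth, accepted = accepted, qc = NULL),
            class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("<gait_cycle '%s': %d samples @ %g Hz, %s%s>\n",
              x$cycle_id, nrow(x$features), x$rate,
              if (is.null(x$vgrf)) "no vGRF" else
                sprintf("vGRF @ %g Hz", x$vgrf$rate),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Cycle metadata as a data frame
#'
#' @param cycles A list of [gait_cycle()] objects.
#' @return One row per cycle with identifiers, conditions, lengths, and QC
#'   status.
#' @export
cycle_metadata <- function(cycles) {
  do.call(rbind, lapply(cycles, function(cy) {
    data.frame(cycle_id = cy$cycle_id, participant_id = cy$participant_id,
               dataset_id = cy$dataset_id, n_samples = nrow(cy$features),
               rate = cy$rate, speed = cy$speed, incline = cy$incline,
               strike_pattern = cy$strike_pattern,
               foot_strike_angle = cy$foot_strike_angle,
               accepted = cy$accepted, stringsAsFactors = FALSE)
  }))
}

#' Segment a continuous trial into gait cycles
#'
#' Divides a trial at the apices (local maxima) of the foot-COM vertical
#' position, the stride convention used throughout the package: cycle k
#' spans `[apex_k, apex_{k+1})`. Plateaus of equal maxima are resolved to
#' their first index.
#'
#' @param foot_com_vertical A [time_series()] of foot-COM vertical position.
#' @param channels Named list of [time_series()] sharing the same time base,
#'   carved up alongside the position signal.
#' @param min_separation Minimum apex spacing in seconds (suppresses
#'   spurious maxima closer than a physiological stride; default 0.4 s).
#' @return A list with `cycles` (list of named channel-segment lists, each
#'   including `foot_vert_pos`), and `apices` (apex sample indices).
#'   Fewer than two apices yields zero cycles with a warning.
#' @export
segment_cycles <- function(foot_com_vertical, channels = list(),
                           min_separation = 0.4) {
  p <- foot_com_vertical$values
  n <- length(p)
  for (ch in channels)
    if (length(ch$values) != n)
      stopf("channel '%s' length %d does not match position length %d",
            ch$name, length(ch$values), n)
  # run-aware strict local maxima: value above the previous distinct value
  # and above the next distinct value; first index of any plateau. A trial
  # that opens descending starts at an apex by the cycle convention.
  apices <- if (n >= 2 && p[1] > p[2]) 1L else integer(0)
  i <- 2L
  while (i < n) {
    j <- i
    while (j < n && p[j + 1] == p[i]) j <- j + 1L
    if (p[i] > p[i - 1] && j < n && p[j + 1] < p[i]) apices <- c(apices, i)
    i <- j + 1L
  }
  if (length(apices) > 1 && min_separation > 0) {
    keep <- apices[1]
    gap <- min_separation * foot_com_vertical$rate
    for (a in apices[-1]) {
      if (a - keep[length(keep)] >= gap) keep <- c(keep, a)
      else if (p[a] > p[keep[length(keep)]]) keep[length(keep)] <- a
    }
    apices <- keep
  }
  if (length(apices) < 2) {
    warnf("fewer than 2 foot-COM apices found; no cycles segmented")
    return(list(cycles = list(), apices = apices))
  }
  cycles <- lapply(seq_len(length(apices) - 1), function(k) {
    idx <- seq(apices[k], apices[k + 1] - 1L)
    seg <- lapply(channels, function(ch)
      time_series(ch$values[idx], ch$rate, ch$name))
    seg$foot_vert_pos <- time_series(p[idx], foot_com_vertical$rate,
                                     "foot_vert_pos")
    seg
  })
  list(cycles = cycles, apices = apices)
}

#' Quality-control filter for vertical GRF unloading
#'
#' Instrumented-treadmill decks can produce aberrant plateaus or bumps in
#' the vGRF as the foot unloads towards toe-off. A cycle is rejected when
#' its terminal unloading interval — from the last downward crossing of
#' 100 N to the subsequent downward crossing of 50 N — contains any
#' frame-to-frame positive loading rate of at least 200 N/s (equivalently
#' 1 N per frame at 200 Hz). Cycles whose vGRF never reaches 100 N are
#' accepted with an "interval absent" diagnostic, since the rule has
#' nothing to examine.
#'
#' @param vgrf A [time_series()] of vertical GRF (N) covering one cycle, or
#'   a [gait_cycle()].
#' @param max_rate Rejection bound in N/s (default 200).
#' @return A list: `accepted` (logical), `max_rate` (largest frame-to-frame
#'   loading rate in the interval, N/s), `interval` (sample index bounds,
#'   or `NULL` when absent), `reason` (text).
#' @examples
#' f <- time_series(c(0, 300, 800, 400, 120, 80, 60, 40, 0), rate = 200)
#' qc_filter(f)$accepted
#' @export
qc_filter <- function(vgrf, max_rate = 200) {
  if (inherits(vgrf, "gait_cycle")) vgrf <- vgrf$vgrf
  stopifnot(inherits(vgrf, "time_series"))
  f <- vgrf$values
  n <- length(f)
  down100 <- which(f[-n] >= 100 & f[-1] < 100)
  if (length(down100) == 0)
    return(list(accepted = TRUE, max_rate = NA_real_, interval = NULL,
                reason = "interval absent: vGRF never drops through 100 N"))
  a <- down100[length(down100)]
  below50 <- which(f < 50)
  below50 <- below50[below50 > a]
  b <- if (length(below50)) below50[1] else n
  rates <- diff(f[a:b]) * vgrf$rate
  mx <- max(rates)
  list(accepted = mx < max_rate, max_rate = mx, interval = c(a, b),
       reason = if (mx < max_rate) "clean unloading"
                else sprintf("positive loading rate %.1f N/s >= %g N/s in the 100->50 N drop",
                             mx, max_rate))
}

#' Apply the QC filter to a set of cycles
#'
#' @param cycles List of [gait_cycle()] objects with vGRF.
#' @param max_rate Rejection bound in N/s.
#' @return The cycles with `accepted` and `qc` fields filled in, plus a
#'   `qc_report` attribute (data frame: cycle id, accepted, max rate).
#' @export
qc_filter_cycles <- function(cycles, max_rate = 200) {
  out <- lapply(cycles, function(cy) {
    q <- qc_filter(cy$vgrf, max_rate)
    cy$accepted <- q$accepted
    cy$qc <- q
    cy
  })
  attr(out, "qc_report") <- do.call(rbind, lapply(out, function(cy)
    data.frame(cycle_id = cy$cycle_id, accepted = cy$accepted,
               max_rate = cy$qc$max_rate, reason = cy$qc$reason,
               stringsAsFactors = FALSE)))
  class(out) <- c("gait_cycle_list", "list")
  out
}

# nearest mocap frame (0-based) for a time in seconds, round-half-up
nearest_mocap_frame <- function(time_s, mocap_rate) {
  as.integer(floor(time_s * mocap_rate + 0.5))
}

#' Build force-derived contact labels and ground-truth events
#'
#' The gold-standard labelling: contact is every force-rate frame with raw
#' vGRF >= 50 N. The first and last contact frames are converted to times
#' and mapped to the closest mocap frame (round-half-up on ties) to give
#' the ground-truth foot-strike and toe-off; the mocap-rate label vector is
#' 1 on `[FS, TO]` inclusive. If thresholding yields more than one contact
#' run the longest is kept with a warning.
#'
#' @param cycle A [gait_cycle()] with a vGRF trace (should have passed
#'   [qc_filter()]).
#' @param threshold Contact threshold in newtons (default 50; a sample
#'   exactly at the threshold counts as contact).
#' @return The cycle with `labels` (0/1 at mocap rate) and `events` (a
#'   one-row [step_events()] data frame) filled in.
#' @export
label_contact <- function(cycle, threshold = 50) {
  stopifnot(inherits(cycle, "gait_cycle"))
  if (is.null(cycle$vgrf)) stopf("cycle '%s' has no vGRF trace", cycle$cycle_id)
  f <- cycle$vgrf$values
  contact <- f >= threshold
  if (!any(contact)) stopf("cycle '%s': no contact (no vGRF sample >= %g N)",
                           cycle$cycle_id, threshold)
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) > 1) {
    warnf("cycle '%s': %d contact runs after thresholding; keeping the longest",
          cycle$cycle_id, length(runs))
    runs <- runs[which.max(r$lengths[runs])]
  }
  fs_force <- starts[runs] - 1L          # 0-based force frames
  to_force <- ends[runs] - 1L
  fr <- cycle$vgrf$rate
  fs <- nearest_mocap_frame(fs_force / fr, cycle$rate)
  to <- nearest_mocap_frame(to_force / fr, cycle$rate)
  n <- nrow(cycle$features)
  fs <- min(fs, n - 1L); to <- min(to, n - 1L)
  labels <- integer(n)
  labels[(fs + 1):(to + 1)] <- 1L
  cycle$labels <- labels
  cycle$events <- step_events(fs, to, cycle$rate, cycle_id = cycle$cycle_id)
  cycle
}

#' Label a set of accepted cycles
#'
#' Runs [qc_filter_cycles()] (unless already applied) and [label_contact()]
#' over a cycle list; rejected cycles keep `labels = NULL`.
#'
#' @param cycles List of [gait_cycle()] objects.
#' @param threshold Contact threshold in newtons.
#' @return Labelled cycle list with the QC report attribute.
#' @export
label_cycles <- function(cycles, threshold = 50) {
  if (all(vapply(cycles, function(cy) is.na(cy$accepted), logical(1))))
    cycles <- qc_filter_cycles(cycles)
  rep_attr <- attr(cycles, "qc_report")
  out <- lapply(cycles, function(cy) {
    if (isTRUE(cy$accepted)) label_contact(cy, threshold) else cy
  })
  attr(out, "qc_report") <- rep_attr
  class(out) <- c("gait_cycle_list", "list")
  out
}

#' Standardise features and zero-pad cycles into a model batch
#'
#' Converts labelled cycles into the fixed-shape arrays the network
#' consumes: per-channel z-scores using the training set's mean and SD
#' (never the validation or test set's — the scaler is fitted once on
#' training data and reused, preventing information leakage), then
#' zero-padding prepended so every cycle is 200 steps long. A mask marks
#' real samples; padded positions hold exact zeros and are skipped by the
#' network and all metrics.
#'
#' @param cycles List of labelled [gait_cycle()] objects (length <= 200
#'   samples each).
#' @param scaler Optional scaler (list with `mean`, `sd` per channel) from
#'   a previous training-set call; when `NULL` the scaler is fitted on
#'   `cycles`, which must then be a training set.
#' @param max_len Padded length (default 200).
#' @return A `padded_batch`: `inputs` (cycles x 200 x 4), `targets`
#'   (cycles x 200), `mask` (cycles x 200), `scaler`, `lengths`,
#'   `cycle_ids`, and `meta` (cycle metadata).
#' @export
standardise_and_pad <- function(cycles, scaler = NULL, max_len = 200L) {
  stopifnot(length(cycles) >= 1)
  lens <- vapply(cycles, function(cy) nrow(cy$features), integer(1))
  too_long <- lens > max_len
  if (any(too_long))
    stopf("cycles longer than %d samples: %s", max_len,
          paste(vapply(cycles[too_long], `[[`, "", "cycle_id"), collapse = ", "))
  channels <- colnames(cycles[[1]]$features)
  if (is.null(scaler)) {
    all_feat <- do.call(rbind, lapply(cycles, `[[`, "features"))
    mu <- colMeans(all_feat)
    sdev <- apply(all_feat, 2, sd)
    if (any(sdev < 1e-12))
      stopf("degenerate channel (zero variance in training data): %s",
            paste(channels[sdev < 1e-12], collapse = ", "))
    scaler <- list(mean = mu, sd = sdev)
  }
  nb <- length(cycles)
  inputs <- array(0, dim = c(nb, max_len, 4L),
                  dimnames = list(NULL, NULL, channels))
  targets <- matrix(0L, nb, max_len)
  mask <- matrix(0L, nb, max_len)
  for (i in seq_len(nb)) {
    z <- sweep(sweep(cycles[[i]]$features, 2, scaler$mean, "-"),
               2, scaler$sd, "/")
    rows <- seq(max_len - lens[i] + 1L, max_len)
    inputs[i, rows, ] <- z
    mask[i, rows] <- 1L
    if (!is.null(cycles[[i]]$labels)) targets[i, rows] <- cycles[[i]]$labels
  }
  structure(list(inputs = inputs, targets = targets, mask = mask,
                 scaler = scaler, lengths = lens,
                 cycle_ids = vapply(cycles, `[[`, "", "cycle_id"),
                 meta = cycle_metadata(cycles)),
            class = "padded_batch")
}

#' @export
print.padded_batch <- function(x, ...) {
  cat(sprintf("<padded_batch: %d cycles x %d steps x %d channels, %d real frames>\n",
              dim(x$inputs)[1], dim(x$inputs)[2], dim(x$inputs)[3],
              sum(x$mask)))
  invisible(x)
}

#' Participant-wise test split and cross-validation folds
#'
#' Splits operate on participants, never on cycles, so no participant's
#' data can leak across partitions. Within each dataset a `test_fraction`
#' of participants (rounded) is drawn for the held-out test set; the
#' remainder are shuffled and dealt round-robin into `n_folds`
#' cross-validation folds, keeping each fold's dataset composition
#' representative. Deterministic given `seed`.
#'
#' @param cycles List of [gait_cycle()] objects.
#' @param test_fraction Fraction of participants per dataset held out
#'   (default 0.30).
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the draw.
#' @return A list: `test` (participant ids), `folds` (list of participant
#'   id vectors), `assignment` (data frame participant_id, dataset_id,
#'   partition), and `cycle_partition` (partition of each cycle, named by
#'   cycle id).
#' @export
split_participants <- function(cycles, test_fraction = 0.30, n_folds = 5L,
                               seed = 1L) {
  meta <- unique(cycle_metadata(cycles)[, c("participant_id", "dataset_id")])
  with_seed(seed, {
    test <- character(0)
    folds <- vector("list", n_folds)
    for (ds in sort(unique(meta$dataset_id))) {
      pids <- sort(meta$participant_id[meta$dataset_id == ds])
      n_test <- round(test_fraction * length(pids))
      test_ds <- if (n_test > 0) sample(pids, n_test) else character(0)
      rest <- sample(setdiff(pids, test_ds))
      if (length(rest) < n_folds)
        stopf("dataset '%s' has %d non-test participants, fewer than n_folds = %d",
              ds, length(rest), n_folds)
      test <- c(test, test_ds)
      for (i in seq_along(rest)) {
        k <- ((i - 1L) %% n_folds) + 1L
        folds[[k]] <- c(folds[[k]], rest[i])
      }
    }
    partition <- stats::setNames(rep(NA_character_, nrow(meta)),
                                 meta$participant_id)
    partition[test] <- "test"
    for (k in seq_len(n_folds)) partition[folds[[k]]] <- sprintf("fold%d", k)
    assignment <- data.frame(participant_id = meta$participant_id,
                             dataset_id = meta$dataset_id,
                             partition = partition[meta$participant_id],
                             row.names = NULL, stringsAsFactors = FALSE)
    cyc_part <- vapply(cycles, function(cy) partition[[cy$participant_id]], "")
    names(cyc_part) <- vapply(cycles, `[[`, "", "cycle_id")
    list(test = sort(test), folds = lapply(folds, sort),
         assignment = assignment, cycle_partition = cyc_part)
  })
}

#' Select cycles belonging to a set of participants
#'
#' @param cycles List of [gait_cycle()] objects.
#' @param participants Participant ids to keep.
#' @param labelled_only Drop cycles without contact labels (QC rejects).
#' @return Filtered cycle list.
#' @export
cycles_for <- function(cycles, participants, labelled_only = TRUE) {
  keep <- vapply(cycles, function(cy) {
    cy$participant_id %in% participants &&
      (!labelled_only || !is.null(cy$labels))
  }, logical(1))
  structure(cycles[keep], class = c("gait_cycle_list", "list"))
}
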