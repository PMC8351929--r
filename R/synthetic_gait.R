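#' Configuration for the synthetic treadmill-gait generator
#'
#' Defines the study conditions the generator emulates: treadmill running
#' across 2.5-5 m/s, a mix of rearfoot/midfoot/forefoot strikers, inclines
#' up to +/-9 degrees, motion capture at 150-200 Hz synchronised with a
#' higher-rate instrumented treadmill, contact phases spanning roughly
#' 30-45% of the gait cycle, and an optional rate of injected vertical-GRF
#' quality-control violations (aberrant bumps in the unloading tail).
#'
#' @param n_participants Number of synthetic participants.
#' @param cycles_per_participant Gait cycles generated per participant.
#' @param speed_range Running speed range in m/s (min, max).
#' @param strike_mix Proportions of rearfoot/midfoot/forefoot strikers;
#'   must sum to 1.
#' @param incline_range Treadmill incline range in degrees (min, max).
#' @param mocap_rate Motion-capture sampling rate in Hz.
#' @param force_rate Force sampling rate in Hz; must be an integer multiple
#'   of `mocap_rate` (simplifies event mapping between the two time bases).
#' @param noise_sd Measurement-noise SD added to the kinematic channels
#'   after ground-truth construction. Either a single number applied to all
#'   six channels or a named vector with entries `tibia_ap_vel`,
#'   `ankle_angle`, `foot_ap_vel`, `foot_vert_vel`, `hip_angle`,
#'   `knee_angle` (velocities in m/s, angles in degrees).
#' @param vgrf_noise_sd Noise SD (N) on the vertical GRF; default 0 so the
#'   force-derived ground truth stays exact (the trace is clipped at 0 N).
#' @param qc_violation_rate Probability that a cycle receives an injected
#'   positive-slope bump in its 100 to 50 N unloading tail, which the
#'   quality-control filter should discard.
#' @param n_datasets Number of synthetic "laboratories" participants are
#'   spread across (used for dataset-stratified splits).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @examples
#' cfg <- synthetic_config(n_participants = 4, cycles_per_participant = 5, seed = 1)
#' @export
synthetic_config <- function(n_participants = 10,
                             cycles_per_participant = 50,
                             speed_range = c(2.5, 5),
                             strike_mix = c(rearfoot = 0.6, midfoot = 0.2,
                                            forefoot = 0.2),
                             incline_range = c(-9, 9),
                             mocap_rate = 200,
                             force_rate = 1000,
                             noise_sd = c(tibia_ap_vel = 0.1, ankle_angle = 1,
                                          foot_ap_vel = 0.1, foot_vert_vel = 0.1,
                                          hip_angle = 1, knee_angle = 1),
                             vgrf_noise_sd = 0,
                             qc_violation_rate = 0,
                             n_datasets = 1,
                             seed = 1L) {
  kin <- c("tibia_ap_vel", "ankle_angle", "foot_ap_vel", "foot_vert_vel",
           "hip_angle", "knee_angle")
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep(as.numeric(noise_sd), 6), kin)
  if (!all(kin %in% names(noise_sd)) || any(noise_sd < 0))
    stopf("noise_sd must be a non-negative scalar or named vector covering: %s",
          paste(kin, collapse = ", "))
  noise_sd <- noise_sd[kin]
  if (length(strike_mix) != 3L || any(strike_mix < 0) ||
      abs(sum(strike_mix) - 1) > 1e-9)
    stopf("strike_mix must be 3 non-negative proportions summing to 1")
  names(strike_mix) <- c("rearfoot", "midfoot", "forefoot")
  if (mocap_rate <= 0 || force_rate <= 0 ||
      abs(force_rate / mocap_rate - round(force_rate / mocap_rate)) > 1e-9)
    stopf("force_rate (%g) must be an integer multiple of mocap_rate (%g)",
          force_rate, mocap_rate)
  if (qc_violation_rate < 0 || qc_violation_rate > 1)
    stopf("qc_violation_rate must lie in [0, 1]")
  if (length(speed_range) != 2L || diff(speed_range) < 0 || speed_range[1] <= 0)
    stopf("speed_range must be an increasing positive pair (m/s)")
  if (length(incline_range) != 2L || diff(incline_range) < 0)
    stopf("incline_range must be an increasing pair (degrees)")
  structure(list(n_participants = as.integer(n_participants),
                 cycles_per_participant = as.integer(cycles_per_participant),
                 speed_range = as.numeric(speed_range),
                 strike_mix = strike_mix,
                 incline_range = as.numeric(incline_range),
                 mocap_rate = as.numeric(mocap_rate),
                 force_rate = as.numeric(force_rate),
                 noise_sd = noise_sd,
                 vgrf_noise_sd = as.numeric(vgrf_noise_sd),
                 qc_violation_rate = as.numeric(qc_violation_rate),
                 n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Ground truth for one synthetic gait cycle
#'
#' Records the quantities the generator commits to before any waveform is
#' built: the cycle duration, the exact contact interval, speed, incline,
#' strike pattern and foot-strike angle. Contact times are snapped to the
#' force-sample grid so that thresholding the noise-free vertical GRF at
#' 50 N recovers them exactly.
#'
#' @param contact_start_time,contact_end_time Contact interval bounds in
#'   seconds from cycle start (the cycle starts at a foot-COM apex).
#' @param duration Cycle duration in seconds.
#' @param speed Belt speed in m/s.
#' @param strike_pattern One of `"rearfoot"`, `"midfoot"`, `"forefoot"`.
#' @param foot_strike_angle Sagittal foot angle at contact in degrees
#'   (positive = dorsiflexed rearfoot strike).
#' @param incline Treadmill incline in degrees.
#' @param has_qc_violation Whether an aberrant unloading-tail bump is
#'   injected into the vertical GRF.
#' @param body_weight Participant body weight in newtons (scales the GRF).
#' @return A `synthetic_cycle_truth` list.
#' @export
synthetic_cycle_truth <- function(contact_start_time, contact_end_time,
                                  duration, speed,
                                  strike_pattern = "rearfoot",
                                  foot_strike_angle = 12,
                                  incline = 0,
                                  has_qc_violation = FALSE,
                                  body_weight = 700) {
  strike_pattern <- match.arg(strike_pattern,
                              c("rearfoot", "midfoot", "forefoot"))
  if (!(0 < contact_start_time && contact_start_time < contact_end_time &&
        contact_end_time < duration))
    stopf("need 0 < contact_start (%g) < contact_end (%g) < duration (%g)",
          contact_start_time, contact_end_time, duration)
  duty <- (contact_end_time - contact_start_time) / duration
  if (duty < 0.2 || duty > 0.5)
    stopf("duty factor %.3f outside the physiological band [0.2, 0.5]", duty)
  structure(list(contact_start_time = contact_start_time,
                 contact_end_time = contact_end_time,
                 duration = duration, speed = speed,
                 strike_pattern = strike_pattern,
                 foot_strike_angle = foot_strike_angle,
                 incline = incline,
                 has_qc_violation = isTRUE(has_qc_violation),
                 body_weight = body_weight),
            class = "synthetic_cycle_truth")
}

# Smooth periodic waveform helpers. All channels are built from half-cosine
# segments and squared-sine bumps that are C1-continuous and phase-locked to
# the contact interval, keeping spectral content well below 10 Hz at
# physiological cycle durations.

# swing-phase coordinate: 0 at toe-off, 1 at the next foot-strike; NA in stance
swing_phase <- function(t, t_fs, t_to, dur) {
  u <- rep(NA_real_, length(t))
  sw <- dur - (t_to - t_fs)
  late <- t >= t_to
  early <- t <= t_fs
  u[late] <- (t[late] - t_to) / sw
  u[early] <- (t[early] + dur - t_to) / sw
  u
}

# stance-phase coordinate in [0, 1]; NA outside contact
stance_phase <- function(t, t_fs, t_to) {
  tau <- (t - t_fs) / (t_to - t_fs)
  tau[tau < 0 | tau > 1] <- NA_real_
  tau
}

half_cos <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2

#' Generate one synthetic gait cycle
#'
#' Builds a complete labelled cycle from a committed ground-truth record:
#' the four kinematic input channels at motion-capture rate, hip/knee
#' sagittal angles and foot-COM vertical position as auxiliary channels,
#' and the vertical GRF at force rate. The cycle starts and ends at a
#' foot-COM vertical-position apex. Before noise, the vGRF is >= 50 N
#' exactly on the committed contact interval and zero outside it, so the
#' 50 N labelling rule recovers the truth; the ankle angle at contact is
#' dorsiflexed (positive) for rearfoot strikes and plantar-flexed
#' (negative) for forefoot strikes; rearfoot cycles carry an impact
#' transient in early stance.
#'
#' @param config A [synthetic_config()].
#' @param truth A [synthetic_cycle_truth()].
#' @param participant_id,dataset_id,cycle_id Metadata attached to the cycle.
#' @param noise Whether to add the configured measurement noise.
#' @return A [gait_cycle()] object.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' tr <- synthetic_cycle_truth(0.15, 0.40, 0.70, speed = 3.5)
#' cyc <- generate_cycle(cfg, tr)
#' @export
generate_cycle <- function(config, truth, participant_id = "P01",
                           dataset_id = "D1", cycle_id = "P01_C001",
                           noise = TRUE) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_cycle_truth"))
  mr <- config$mocap_rate; fr <- config$force_rate
  ratio <- as.integer(round(fr / mr))
  n_mocap <- as.integer(round(truth$duration * mr))
  if (n_mocap > 200L)
    stopf("cycle of %.3f s spans %d samples at %g Hz, above the 200-sample input limit",
          truth$duration, n_mocap, mr)
  dur <- n_mocap / mr
  # snap contact bounds to the force grid so 50 N labelling is exact
  t_fs <- round(truth$contact_start_time * fr) / fr
  t_to <- round(truth$contact_end_time * fr) / fr
  t_fs <- max(t_fs, 1 / fr)
  t_to <- min(t_to, dur - 1 / fr)
  truth$contact_start_time <- t_fs
  truth$contact_end_time <- t_to
  truth$duration <- dur

  tm <- (seq_len(n_mocap) - 1) / mr          # mocap time base
  n_force <- n_mocap * ratio
  tf <- (seq_len(n_force) - 1) / fr          # force time base

  speed <- truth$speed
  duty <- (t_to - t_fs) / dur
  swing_frac <- 1 - duty

  ## ---- vertical GRF (force rate) ----
  tau_f <- stance_phase(tf, t_fs, t_to)
  in_contact <- !is.na(tau_f)
  f_peak <- truth$body_weight * (2.2 + 0.25 * (speed - 2.5))
  vgrf <- numeric(n_force)
  vgrf[in_contact] <- 50 + (f_peak - 50) * sin(pi * tau_f[in_contact])^2
  if (truth$strike_pattern == "rearfoot") {
    imp <- 0.35 * truth$body_weight *
      exp(-0.5 * ((tau_f[in_contact] - 0.12) / 0.04)^2)
    vgrf[in_contact] <- vgrf[in_contact] + imp
  }
  if (truth$has_qc_violation) {
    # brief positive-slope bump inside the terminal 100 -> 50 N drop
    idx <- which(in_contact & tau_f > 0.5)
    tail_idx <- idx[vgrf[idx] < 95 & vgrf[idx] > 60]
    if (length(tail_idx) >= 4) {
      j <- tail_idx[ceiling(length(tail_idx) / 2)]
      step <- 400 / fr   # 400 N/s rise, twice the 200 N/s rejection bound
      vgrf[j + 1] <- vgrf[j] + step
      vgrf[j + 2] <- vgrf[j + 1]
    }
  }

  ## ---- kinematic channels (mocap rate) ----
  u <- swing_phase(tm, t_fs, t_to, dur)      # NA during stance
  swing_bump <- ifelse(is.na(u), 0, sin(pi * u)^2)
  tau <- stance_phase(tm, t_fs, t_to)
  stance_bump <- ifelse(is.na(tau), 0, sin(pi * tau)^2)

  # foot COM vertical position: apex at the cycle boundaries, flat in stance
  step_h <- 0.12 + 0.02 * (speed - 2.5)
  pos <- numeric(n_mocap)
  pre <- tm <= t_fs
  post <- tm >= t_to
  pos[pre] <- step_h * (1 - half_cos(tm[pre] / t_fs))
  pos[post] <- step_h * half_cos((tm[post] - t_to) / (dur - t_to))
  # analytic derivative of pos, then exact discrete mean removal (periodicity)
  vvel <- numeric(n_mocap)
  vvel[pre] <- -step_h * pi / (2 * t_fs) * sin(pi * pmin(tm[pre] / t_fs, 1))
  vvel[post] <- step_h * pi / (2 * (dur - t_to)) *
    sin(pi * pmin((tm[post] - t_to) / (dur - t_to), 1))
  vvel <- vvel - mean(vvel)

  # foot COM AP velocity: -belt speed in stance, forward swing-through
  a_sw <- 2 * speed / swing_frac
  foot_ap <- -speed + a_sw * swing_bump

  # distal tibia AP velocity: attenuated version plus a cycle harmonic
  a_tib <- 2 * 0.85 * speed / swing_frac
  tib_ap <- -0.85 * speed + a_tib * swing_bump +
    0.25 * speed * sin(2 * pi * tm / dur + 0.4)

  # ankle dorsi(+)/plantar(-) flexion: strike-pattern angle at contact,
  # dorsiflexion in mid-stance, plantar flexion push-off at toe-off
  fsa <- truth$foot_strike_angle
  ank <- numeric(n_mocap)
  st <- !is.na(tau)
  mid <- 0.45
  early <- st & tau <= mid
  late <- st & tau > mid
  ank[early] <- fsa + (15 - fsa) * half_cos(tau[early] / mid)
  ank[late] <- 15 + (-18 - 15) * half_cos((tau[late] - mid) / (1 - mid))
  sw <- !st
  ank[sw] <- -18 + (fsa + 18) * half_cos(u[sw])

  # hip flexion(+): peak just before foot-strike, extension through stance
  hip <- 10 - 0.3 * truth$incline + 22 * cos(2 * pi * (tm - t_fs) / dur) +
    3 * cos(4 * pi * (tm - t_fs) / dur + 1)

  # knee flexion(+): stance absorption bump plus large swing flexion
  knee <- 18 + 24 * stance_bump + (70 + 6 * (speed - 2.5)) * swing_bump

  feat <- cbind(tibia_ap_vel = tib_ap, ankle_angle = ank,
                foot_ap_vel = foot_ap, foot_vert_vel = vvel)
  aux <- cbind(hip_angle = hip, knee_angle = knee, foot_vert_pos = pos)

  if (isTRUE(noise)) {
    ns <- config$noise_sd
    for (ch in colnames(feat))
      feat[, ch] <- feat[, ch] + rnorm(n_mocap, 0, ns[[ch]])
    for (ch in c("hip_angle", "knee_angle"))
      aux[, ch] <- aux[, ch] + rnorm(n_mocap, 0, ns[[ch]])
    if (config$vgrf_noise_sd > 0)
      vgrf <- pmax(0, vgrf + rnorm(n_force, 0, config$vgrf_noise_sd))
  }

  gait_cycle(features = feat, rate = mr,
             vgrf = time_series(vgrf, fr, "vgrf"),
             aux = aux,
             participant_id = participant_id, dataset_id = dataset_id,
             cycle_id = cycle_id, speed = speed, incline = truth$incline,
             strike_pattern = truth$strike_pattern,
             foot_strike_angle = fsa, truth = truth)
}

# deterministic largest-remainder allocation of participants to strike patterns
allocate_strike_patterns <- function(n, mix) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  rep(names(mix), times = base)
}

#' Generate a full synthetic dataset of gait cycles
#'
#' Draws per-participant characteristics (strike pattern per the configured
#' mix, body weight, cadence offset, habitual foot-strike angle) and then
#' per-cycle conditions (speed, incline, timing jitter, QC-violation flag)
#' and renders every cycle with [generate_cycle()]. Cycle duration and duty
#' factor shorten with speed (roughly 0.9 s / 45% contact at 2.5 m/s down
#' to 0.6 s / 30% at 5 m/s). Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of [gait_cycle()] objects (class `gait_cycle_list`) with
#'   the config attached as attribute `config`.
#' @examples
#' cycles <- generate_dataset(synthetic_config(n_participants = 2,
#'                                             cycles_per_participant = 3,
#'                                             seed = 7))
#' length(cycles)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    np <- config$n_participants
    patterns <- allocate_strike_patterns(np, config$strike_mix)
    patterns <- sample(patterns)                # shuffle assignment order
    pids <- sprintf("P%02d", seq_len(np))
    dids <- sprintf("D%d", rep_len(seq_len(config$n_datasets), np))
    cycles <- vector("list", np * config$cycles_per_participant)
    k <- 0L
    for (p in seq_len(np)) {
      pat <- patterns[p]
      bw <- rnorm(1, 700, 70)
      dur_off <- rnorm(1, 0, 0.03)
      fsa_mean <- switch(pat,
                         rearfoot = runif(1, 8, 20),
                         midfoot = runif(1, -3, 3),
                         forefoot = runif(1, -18, -6))
      for (cc in seq_len(config$cycles_per_participant)) {
        speed <- runif(1, config$speed_range[1], config$speed_range[2])
        incline <- runif(1, config$incline_range[1], config$incline_range[2])
        dur <- min(max(0.9 - 0.12 * (speed - 2.5) + dur_off +
                         rnorm(1, 0, 0.01), 0.55), 0.99)
        duty <- min(max(0.45 - 0.055 * (speed - 2.5) + rnorm(1, 0, 0.015),
                        0.24), 0.48)
        start_frac <- runif(1, 0.18, 0.28)
        fsa <- fsa_mean + rnorm(1, 0, 1)
        viol <- rbinom(1, 1, config$qc_violation_rate) == 1
        truth <- synthetic_cycle_truth(
          contact_start_time = start_frac * dur,
          contact_end_time = (start_frac + duty) * dur,
          duration = dur, speed = speed, strike_pattern = pat,
          foot_strike_angle = fsa, incline = incline,
          has_qc_violation = viol, body_weight = bw)
        k <- k + 1L
        cycles[[k]] <- generate_cycle(config, truth,
                                      participant_id = pids[p],
                                      dataset_id = dids[p],
                                      cycle_id = sprintf("%s_C%03d", pids[p], cc))
      }
    }
    structure(cycles, class = c("gait_cycle_list", "list"), config = config)
  })
}

#' Concatenate cycles into a continuous trial
#'
#' Joins per-cycle channels end-to-end to emulate a continuous treadmill
#' trial, mainly so that [segment_cycles()] can be exercised against known
#' cycle boundaries. Returns the foot-COM vertical position together with
#' all kinematic channels on the shared mocap time base.
#'
#' @param cycles A list of [gait_cycle()] objects at a common mocap rate.
#' @return A list with `foot_vert_pos` (a [time_series()]), `channels`
#'   (named list of `time_series`), and `boundaries` (start indices of each
#'   cycle in the concatenated trial).
#' @export
concatenate_cycles <- function(cycles) {
  stopifnot(length(cycles) >= 1)
  rate <- cycles[[1]]$rate
  lens <- vapply(cycles, function(cy) nrow(cy$features), integer(1))
  pos <- unlist(lapply(cycles, function(cy) cy$aux[, "foot_vert_pos"]))
  chans <- c(colnames(cycles[[1]]$features), "hip_angle", "knee_angle")
  channels <- lapply(chans, function(ch) {
    v <- unlist(lapply(cycles, function(cy) {
      if (ch %in% colnames(cy$features)) cy$features[, ch] else cy$aux[, ch]
    }))
    time_series(v, rate, ch)
  })
  names(channels) <- chans
  list(foot_vert_pos = time_series(pos, rate, "foot_vert_pos"),
       channels = channels,
       boundaries = cumsum(c(1L, lens[-length(lens)])))
}
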