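# CSV interchange dialect
#
# A cycle set is written as two files:
#   * a data CSV with one row per force-rate sample, columns
#     participant_id, cycle_id, time_s, tibia_ap_vel, ankle_angle,
#     foot_ap_vel, foot_vert_vel, hip_angle, knee_angle, foot_vert_pos,
#     vgrf. Kinematic columns are populated on mocap-aligned rows and NA
#     between them (the force rate is an integer multiple of the mocap
#     rate); when no force trace exists rows are at mocap rate and vgrf is
#     absent. Times in seconds, angles in degrees, forces in newtons.
#   * a metadata CSV with one row per cycle: ids, rates, conditions, and —
#     for synthetic cycles — the ground-truth contact interval.

#' Write gait cycles to CSV
#'
#' @param cycles List of [gait_cycle()] objects.
#' @param data_path Path for the sample-level CSV.
#' @param meta_path Path for the cycle-level metadata CSV (default: data
#'   path with `_meta` inserted).
#' @return Invisibly, the two paths.
#' @export
write_cycles_csv <- function(cycles, data_path,
                             meta_path = sub("(\\.csv)?$", "_meta.csv",
                                             data_path)) {
  rows <- lapply(cycles, function(cy) {
    n_kin <- nrow(cy$features)
    if (!is.null(cy$vgrf)) {
      ratio <- as.integer(round(cy$vgrf$rate / cy$rate))
      n <- length(cy$vgrf$values)
      tt <- (seq_len(n) - 1) / cy$vgrf$rate
      kin_row <- rep(NA_integer_, n)
      kin_row[seq(1, by = ratio, length.out = n_kin)] <- seq_len(n_kin)
      kin <- function(v) ifelse(is.na(kin_row), NA_real_, v[kin_row])
      df <- data.frame(participant_id = cy$participant_id,
                       cycle_id = cy$cycle_id, time_s = tt,
                       tibia_ap_vel = kin(cy$features[, "tibia_ap_vel"]),
                       ankle_angle = kin(cy$features[, "ankle_angle"]),
                       foot_ap_vel = kin(cy$features[, "foot_ap_vel"]),
                       foot_vert_vel = kin(cy$features[, "foot_vert_vel"]),
                       hip_angle = kin(cy$aux[, "hip_angle"]),
                       knee_angle = kin(cy$aux[, "knee_angle"]),
                       foot_vert_pos = kin(cy$aux[, "foot_vert_pos"]),
                       vgrf = cy$vgrf$values, stringsAsFactors = FALSE)
    } else {
      df <- data.frame(participant_id = cy$participant_id,
                       cycle_id = cy$cycle_id,
                       time_s = (seq_len(n_kin) - 1) / cy$rate,
                       tibia_ap_vel = cy$features[, "tibia_ap_vel"],
                       ankle_angle = cy$features[, "ankle_angle"],
                       foot_ap_vel = cy$features[, "foot_ap_vel"],
                       foot_vert_vel = cy$features[, "foot_vert_vel"],
                       hip_angle = cy$aux[, "hip_angle"],
                       knee_angle = cy$aux[, "knee_angle"],
                       foot_vert_pos = cy$aux[, "foot_vert_pos"],
                       stringsAsFactors = FALSE)
    }
    df
  })
  write.csv(do.call(rbind, rows), data_path, row.names = FALSE)
  meta <- do.call(rbind, lapply(cycles, function(cy) {
    tr <- cy$truth
    data.frame(cycle_id = cy$cycle_id, participant_id = cy$participant_id,
               dataset_id = cy$dataset_id, mocap_rate = cy$rate,
               force_rate = if (is.null(cy$vgrf)) NA_real_ else cy$vgrf$rate,
               speed = cy$speed, incline = cy$incline,
               strike_pattern = cy$strike_pattern,
               foot_strike_angle = cy$foot_strike_angle,
               contact_start_s = if (is.null(tr)) NA_real_ else
                 tr$contact_start_time,
               contact_end_s = if (is.null(tr)) NA_real_ else
                 tr$contact_end_time,
               duration_s = nrow(cy$features) / cy$rate,
               body_weight = if (is.null(tr)) NA_real_ else tr$body_weight,
               has_qc_violation = if (is.null(tr)) NA else
                 tr$has_qc_violation,
               stringsAsFactors = FALSE)
  }))
  write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(data = data_path, meta = meta_path))
}

#' Read gait cycles from CSV
#'
#' Reads the dialect written by [write_cycles_csv()] (or user-supplied
#' equivalents). Required data columns: `participant_id`, `cycle_id`,
#'   `time_s` and the four feature channels; `vgrf` is optional — without
#' it cycles load with a warning and contact labels cannot be built.
#'
#' @param data_path Sample-level CSV path.
#' @param meta_path Metadata CSV path.
#' @return A `gait_cycle_list`.
#' @export
read_cycles_csv <- function(data_path,
                            meta_path = sub("(\\.csv)?$", "_meta.csv",
                                            data_path)) {
  df <- read.csv(data_path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stopf("no data rows in %s", data_path)
  required <- c("participant_id", "cycle_id", "time_s", "tibia_ap_vel",
                "ankle_angle", "foot_ap_vel", "foot_vert_vel")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("missing required column(s) in %s: %s", data_path,
          paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(names(df), c("participant_id", "cycle_id"))
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))) &
                     !is.na(df[[cc]]) & df[[cc]] != "")
      stopf("non-numeric value in column '%s' of %s (first at data row %d)",
            cc, data_path, if (length(bad)) bad[1] else NA_integer_)
    }
  }
  has_vgrf <- "vgrf" %in% names(df)
  if (!has_vgrf)
    warnf("no 'vgrf' column in %s: cycles load without force traces; contact labels unavailable",
          data_path)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  cycles <- lapply(split(df, factor(df$cycle_id, unique(df$cycle_id))),
                   function(d) {
    m <- meta[meta$cycle_id == d$cycle_id[1], ]
    if (nrow(m) != 1)
      stopf("cycle '%s' has %d metadata rows", d$cycle_id[1], nrow(m))
    kin_rows <- which(!is.na(d$tibia_ap_vel))
    feat <- as.matrix(d[kin_rows, c("tibia_ap_vel", "ankle_angle",
                                    "foot_ap_vel", "foot_vert_vel")])
    rownames(feat) <- NULL
    aux <- if (all(c("hip_angle", "knee_angle", "foot_vert_pos") %in%
                     names(d)))
      as.matrix(d[kin_rows, c("hip_angle", "knee_angle", "foot_vert_pos")])
    else NULL
    if (!is.null(aux)) rownames(aux) <- NULL
    truth <- if (!is.na(m$contact_start_s))
      synthetic_cycle_truth(m$contact_start_s, m$contact_end_s,
                            m$duration_s, m$speed,
                            strike_pattern = m$strike_pattern,
                            foot_strike_angle = m$foot_strike_angle,
                            incline = m$incline,
                            has_qc_violation = isTRUE(m$has_qc_violation),
                            body_weight = m$body_weight)
    else NULL
    gait_cycle(features = feat, rate = as.numeric(m$mocap_rate),
               vgrf = if (has_vgrf)
                 time_series(d$vgrf, as.numeric(m$force_rate), "vgrf")
               else NULL,
               aux = aux, participant_id = m$participant_id,
               dataset_id = m$dataset_id, cycle_id = m$cycle_id,
               speed = m$speed, incline = m$incline,
               strike_pattern = m$strike_pattern,
               foot_strike_angle = m$foot_strike_angle, truth = truth)
  })
  ids <- vapply(cycles, `[[`, "", "cycle_id")
  structure(unname(cycles[order(match(ids, meta$cycle_id))]),
            class = c("gait_cycle_list", "list"))
}

#' Serialise a trained model to a self-describing JSON file
#'
#' Stores the architecture configuration, the training scaler and every
#' weight tensor at full precision, so a model round-trips exactly.
#'
#' @param model A `stridenet_model`.
#' @param path Output path (.json).
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  payload <- list(
    format = "stridenet_model",
    config = unclass(model$config),
    input_size = model$input_size,
    scaler = if (is.null(model$scaler)) NULL else
      list(channels = names(model$scaler$mean),
           mean = unname(model$scaler$mean),
           sd = unname(model$scaler$sd)),
    best_epoch = model$best_epoch,
    weights = tree_map(function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
      else list(dim = length(x), data = as.numeric(x))
    }, get_weights(model)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model written by [write_model()]
#'
#' @param path JSON path.
#' @return A `stridenet_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "stridenet_model"))
    stopf("%s is not a stridenet model file", path)
  cfg <- do.call(model_config, payload$config[setdiff(names(payload$config),
                                                      character(0))])
  unflatten <- function(node) {
    if (is.list(node) && identical(sort(names(node)), c("data", "dim"))) {
      if (length(node$dim) == 2) matrix(node$data, node$dim[1], node$dim[2])
      else as.numeric(node$data)
    } else lapply(node, unflatten)
  }
  w <- unflatten(payload$weights)
  model <- structure(list(layers = w$layers, dense = w$dense, out = w$out,
                          config = cfg,
                          input_size = as.integer(payload$input_size),
                          scaler = payload$scaler,
                          best_epoch = payload$best_epoch),
                     class = "stridenet_model")
  if (!is.null(model$scaler)) {
    ch <- unlist(model$scaler$channels)
    model$scaler <- list(mean = stats::setNames(unlist(model$scaler$mean), ch),
                         sd = stats::setNames(unlist(model$scaler$sd), ch))
  }
  model
}
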