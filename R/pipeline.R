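#' Resolve a pipeline run configuration
#'
#' Merges user settings (an R list or a flat YAML key-value file) over the
#' package defaults. The resolved configuration is written next to every
#' run's outputs (`config_used.yaml`) so any artefact can be reproduced
#' from its directory alone.
#'
#' @param config Path to a YAML file, or a named list; `NULL` for pure
#'   defaults.
#' @param ... Individual overrides applied last (e.g. `seed = 7`).
#' @return A `run_config` list with elements `out_dir`, `seed`,
#'   `threshold`, `test_fraction`, `n_folds`, `synthetic` (a
#'   [synthetic_config()]) and `model` (a [model_config()]).
#' @export
run_config <- function(config = NULL, ...) {
  user <- list()
  if (is.character(config)) user <- yaml::read_yaml(config)
  else if (is.list(config)) user <- config
  user <- utils::modifyList(user, list(...))
  base <- list(out_dir = "stridenet_run", seed = 1L, threshold = 0.5,
               test_fraction = 0.30, n_folds = 5L, scaled_down = TRUE,
               n_participants = 10L, cycles_per_participant = 50L,
               speed_min = 2.5, speed_max = 5, incline_min = -9,
               incline_max = 9, mocap_rate = 200, force_rate = 1000,
               noise_sd = NULL, qc_violation_rate = 0.02, n_datasets = 1L,
               dropout = 0.5, max_epochs = 100L, patience = 10L,
               batch_size = 200L, learning_rate = 1e-3)
  cfg <- utils::modifyList(base, user)
  syn_args <- list(n_participants = cfg$n_participants,
                   cycles_per_participant = cfg$cycles_per_participant,
                   speed_range = c(cfg$speed_min, cfg$speed_max),
                   incline_range = c(cfg$incline_min, cfg$incline_max),
                   mocap_rate = cfg$mocap_rate, force_rate = cfg$force_rate,
                   qc_violation_rate = cfg$qc_violation_rate,
                   n_datasets = cfg$n_datasets, seed = cfg$seed)
  if (!is.null(cfg$noise_sd)) syn_args$noise_sd <- cfg$noise_sd
  cfg$synthetic <- do.call(synthetic_config, syn_args)
  cfg$model <- model_config(dropout = cfg$dropout,
                            max_epochs = cfg$max_epochs,
                            patience = cfg$patience,
                            batch_size = cfg$batch_size,
                            learning_rate = cfg$learning_rate,
                            seed = cfg$seed,
                            scaled_down = isTRUE(cfg$scaled_down))
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(out_dir, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  sprintf(fmt, ...))
  cat(line, "\n", sep = "", file = file.path(out_dir, "run.log"),
      append = TRUE)
  message(line)
}

flat_config <- function(cfg) {
  keep <- !vapply(cfg, is.list, logical(1))
  out <- cfg[keep]
  out$noise_sd <- paste(cfg$synthetic$noise_sd, collapse = ",")
  out
}

#' Run the detection pipeline end to end
#'
#' Chains the package stages, each runnable independently because every
#' stage reads its inputs from and writes its artefacts to `out_dir`:
#' \describe{
#'   \item{synth}{generate synthetic cycles; writes `cycles.csv` +
#'     `cycles_meta.csv`.}
#'   \item{prepare}{QC-filter, label, and split participants; writes
#'     `qc_report.csv`, `events_truth.csv`, `splits.json`.}
#'   \item{crossval}{participant-wise cross-validation and final refit;
#'     writes `fold_report.csv`, `model.json`, `history.csv`.}
#'   \item{train}{single training run (folds 2..k train, fold 1
#'     validation) as a faster alternative to `crossval`; writes
#'     `model.json`, `history.csv`.}
#'   \item{detect}{predict contact on held-out test participants; writes
#'     `events_pred.csv`.}
#'   \item{evaluate}{agreement statistics against the force-derived ground
#'     truth; writes `agreement.csv` and `agreement.txt`.}
#'   \item{sensitivity}{joint-angle sensitivity grid on test cycles;
#'     writes `sensitivity.csv`.}
#' }
#'
#' @param config A [run_config()] (or anything accepted by it).
#' @param stages Character vector of stages, in order.
#' @return Invisibly, a named list of stage artefact paths.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("synth", "prepare", "crossval", "detect",
                                    "evaluate", "sensitivity")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(flat_config(cfg), file.path(cfg$out_dir,
                                               "config_used.yaml"))
  paths <- list()
  pth <- function(f) file.path(cfg$out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f)))
      stopf("stage '%s' needs missing artefact %s (run earlier stages first)",
            stage, pth(f))
    pth(f)
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    switch(stage,
      synth = {
        cycles <- generate_dataset(cfg$synthetic)
        write_cycles_csv(cycles, pth("cycles.csv"), pth("cycles_meta.csv"))
        pipeline_log(cfg$out_dir, "synth: %d cycles from %d participants",
                     length(cycles), cfg$synthetic$n_participants)
      },
      prepare = {
        cycles <- read_cycles_csv(need("cycles.csv", stage),
                                  pth("cycles_meta.csv"))
        cycles <- label_cycles(cycles)
        write.csv(attr(cycles, "qc_report"), pth("qc_report.csv"),
                  row.names = FALSE)
        truth_events <- do.call(rbind, lapply(
          Filter(function(cy) !is.null(cy$events), cycles), `[[`, "events"))
        write.csv(truth_events, pth("events_truth.csv"), row.names = FALSE)
        splits <- split_participants(cycles, cfg$test_fraction, cfg$n_folds,
                                     seed = cfg$seed)
        jsonlite::write_json(splits[c("test", "folds")], pth("splits.json"))
        pipeline_log(cfg$out_dir,
                     "prepare: %d/%d cycles accepted; %d test participants, %d folds",
                     sum(vapply(cycles, function(cy) isTRUE(cy$accepted),
                                logical(1))),
                     length(cycles), length(splits$test), cfg$n_folds)
      },
      crossval = ,
      train = {
        cycles <- label_cycles(read_cycles_csv(need("cycles.csv", stage),
                                               pth("cycles_meta.csv")))
        splits <- jsonlite::read_json(need("splits.json", stage),
                                      simplifyVector = TRUE)
        if (stage == "crossval") {
          cv <- cross_validate(cycles, splits, cfg$model)
          write.csv(cv$fold_results, pth("fold_report.csv"),
                    row.names = FALSE)
          model <- cv$final_model
          pipeline_log(cfg$out_dir,
                       "crossval: accuracy %.4f +/- %.4f over %d folds; final model refitted (best fold %d)",
                       cv$mean_accuracy, cv$sd_accuracy,
                       nrow(cv$fold_results), cv$best_fold)
        } else {
          tr_cycles <- cycles_for(cycles, unlist(splits$folds[-1]))
          va_cycles <- cycles_for(cycles, splits$folds[[1]])
          tr <- standardise_and_pad(tr_cycles)
          va <- standardise_and_pad(va_cycles, scaler = tr$scaler)
          model <- train_model(cfg$model, tr, va)
          pipeline_log(cfg$out_dir, "train: %d epochs, best epoch %d",
                       nrow(model$history), model$best_epoch)
        }
        write.csv(model$history, pth("history.csv"), row.names = FALSE)
        write_model(model, pth("model.json"))
      },
      detect = {
        model <- read_model(need("model.json", stage))
        cycles <- label_cycles(read_cycles_csv(need("cycles.csv", stage),
                                               pth("cycles_meta.csv")))
        splits <- jsonlite::read_json(need("splits.json", stage),
                                      simplifyVector = TRUE)
        test_cycles <- cycles_for(cycles, splits$test)
        batch <- standardise_and_pad(test_cycles, scaler = model$scaler)
        pred <- predict_contact(model, batch)
        events <- extract_events_batch(pred, threshold = cfg$threshold)
        write.csv(events, pth("events_pred.csv"), row.names = FALSE)
        acc <- frame_accuracy(pred, batch$targets)
        writeLines(sprintf("%.6f", acc), pth("frame_accuracy.txt"))
        pipeline_log(cfg$out_dir,
                     "detect: %d test cycles, frame accuracy %.4f",
                     nrow(events), acc)
      },
      evaluate = {
        pred <- read.csv(need("events_pred.csv", stage))
        truth <- read.csv(need("events_truth.csv", stage))
        truth <- truth[truth$cycle_id %in% pred$cycle_id, ]
        errs <- event_errors(pred, truth)
        acc <- as.numeric(readLines(pth("frame_accuracy.txt")))
        rep <- agreement_report(errs, frame_accuracy = acc)
        write.csv(rep, pth("agreement.csv"), row.names = FALSE)
        sink(pth("agreement.txt")); print(rep); sink()
        pipeline_log(cfg$out_dir,
                     "evaluate: FS RMSE %.2f ms, TO RMSE %.2f ms, CT RMSE %.2f ms",
                     rep$rmse_ms[1], rep$rmse_ms[2], rep$rmse_ms[3])
      },
      sensitivity = {
        cycles <- label_cycles(read_cycles_csv(need("cycles.csv", stage),
                                               pth("cycles_meta.csv")))
        splits <- jsonlite::read_json(need("splits.json", stage),
                                      simplifyVector = TRUE)
        test_cycles <- cycles_for(cycles, splits$test)
        truth_events <- do.call(rbind, lapply(test_cycles, `[[`, "events"))
        grid <- angle_sensitivity(test_cycles, truth_events)
        write.csv(grid, pth("sensitivity.csv"), row.names = FALSE)
        pipeline_log(cfg$out_dir, "sensitivity: %d cells, %d unacceptable",
                     nrow(grid), sum(grid$band == "unacceptable"))
      },
      stopf("unknown stage '%s'", stage))
    pipeline_log(cfg$out_dir, "stage %s done in %.1f s", stage,
                 proc.time()[["elapsed"]] - t0)
  }
  invisible(lapply(stats::setNames(nm = list.files(cfg$out_dir)), pth))
}
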