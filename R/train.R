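# --- weight-tree helpers -------------------------------------------------

get_weights <- function(model) model[c("layers", "dense", "out")]

set_weights <- function(model, w) {
  model$layers <- w$layers
  model$dense <- w$dense
  model$out <- w$out
  model
}

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) mapply(function(x, y) tree_map2(f, x, y), a, b,
                         SIMPLIFY = FALSE)
  else f(a, b)
}

# --- backward pass -------------------------------------------------------

# gradients of the masked BCE loss w.r.t. every weight tensor
model_backward <- function(model, fw, targets, dropout_masks = NULL) {
  cache <- fw$cache
  cfg <- model$config
  B <- cache$B; T <- cache$T
  maskm <- fw$mask
  n_real <- sum(maskm)
  dlog <- as.numeric((fw$prob - targets) * maskm / n_real)

  grads <- list(layers = list(), dense = NULL, out = NULL)
  grads$out <- list(W = crossprod(cache$D, dlog), b = sum(dlog))
  dD <- outer(dlog, as.numeric(model$out$W))
  if (!is.null(dropout_masks))
    dD <- dD * dropout_masks[[cfg$lstm_layers + 1]]
  dDpre <- dD * (cache$Dpre > 0)
  grads$dense <- list(W = crossprod(cache$Hmat, dDpre), b = colSums(dDpre))
  dHmat <- dDpre %*% t(model$dense$W)
  H2 <- ncol(dHmat)
  dHcat <- aperm(array(dHmat, c(B, T, H2)), c(1, 3, 2))

  H <- cfg$lstm_units
  for (l in rev(seq_len(cfg$lstm_layers))) {
    if (!is.null(dropout_masks)) dHcat <- dHcat * dropout_masks[[l]]
    dHf <- dHcat[, seq_len(H), , drop = FALSE]
    dHb <- dHcat[, H + seq_len(H), , drop = FALSE]
    Xl <- cache$X[[l]]
    ff <- cache$lstm[[l]]$fwd
    bb <- cache$lstm[[l]]$bwd
    Wf <- model$layers[[sprintf("l%d_fwd", l)]]
    Wb <- model$layers[[sprintf("l%d_bwd", l)]]
    gf <- .lstm_backward_cpp(Xl, Wf$W, maskm, FALSE, ff$H, ff$gates, ff$C, dHf)
    gb <- .lstm_backward_cpp(Xl, Wb$W, maskm, TRUE, bb$H, bb$gates, bb$C, dHb)
    grads$layers[[sprintf("l%d_fwd", l)]] <- list(W = gf$dW,
                                                  b = as.numeric(gf$db))
    grads$layers[[sprintf("l%d_bwd", l)]] <- list(W = gb$dW,
                                                  b = as.numeric(gb$db))
    if (l > 1) dHcat <- gf$dX + gb$dX
  }
  grads$layers <- grads$layers[names(model$layers)]
  grads
}

# --- Adam ----------------------------------------------------------------

adam_init <- function(w) {
  list(m = tree_map(function(x) x * 0, w), v = tree_map(function(x) x * 0, w),
       t = 0L)
}

adam_step <- function(w, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / corr1) / (sqrt(v / corr2) + eps),
                   state$m, state$v)
  list(w = tree_map2(`-`, w, upd), state = state)
}

# inverted-dropout masks for one mini-batch (NULL when rate is 0)
make_dropout_masks <- function(cfg, B, T, rate) {
  if (rate <= 0) return(NULL)
  H2 <- 2L * cfg$lstm_units
  keep <- 1 / (1 - rate)
  masks <- vector("list", cfg$lstm_layers + 1L)
  for (l in seq_len(cfg$lstm_layers))
    masks[[l]] <- array((runif(B * H2 * T) >= rate) * keep, c(B, H2, T))
  masks[[cfg$lstm_layers + 1L]] <-
    matrix((runif(B * T * cfg$dense_units) >= rate) * keep,
           B * T, cfg$dense_units)
  masks
}

batch_slice <- function(batch, idx) {
  list(inputs = batch$inputs[idx, , , drop = FALSE],
       targets = batch$targets[idx, , drop = FALSE] + 0,
       mask = batch$mask[idx, , drop = FALSE] + 0)
}

# one fused C++ forward (+ optional backward) pass over a mini-batch;
# numerically identical to model_forward() + model_backward(), but no
# activation cache ever crosses the R boundary
train_step <- function(model, inputs, mask, targets, dropout_masks = NULL,
                       compute_grads = TRUE) {
  L <- model$config$lstm_layers
  step <- .train_step_cpp(aperm(inputs, c(1, 3, 2)), mask + 0, targets + 0,
                          model$layers, model$dense$W, model$dense$b,
                          as.numeric(model$out$W), model$out$b,
                          if (is.null(dropout_masks)) list()
                          else dropout_masks[seq_len(L)],
                          if (is.null(dropout_masks)) NULL
                          else dropout_masks[[L + 1L]],
                          compute_grads)
  if (compute_grads) {
    names(step$grads$layers) <- names(model$layers)
    step$grads$out$W <- matrix(step$grads$out$W, ncol = 1)
  }
  step
}

evaluate_batch <- function(model, batch) {
  step <- train_step(model, batch$inputs, batch$mask, batch$targets,
                     compute_grads = FALSE)
  list(loss = step$loss,
       accuracy = masked_accuracy(step$prob, batch$targets, batch$mask))
}

#' Train the contact classifier
#'
#' Stochastic-gradient training with masked binary cross-entropy, Adam,
#' inverted dropout after each hidden layer, mini-batches of
#' `config$batch_size` cycles, and early stopping on masked validation
#' frame accuracy: training stops once `config$patience` epochs pass
#' without strict improvement and the best-scoring weights are restored.
#' Padded frames carry zero loss and zero gradient throughout. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [model_config()].
#' @param train A `padded_batch` standardised with its own (training)
#'   scaler.
#' @param val Optional validation `padded_batch`, standardised with the
#'   training scaler. When `NULL`, training runs for exactly `epochs`
#'   epochs with no early stopping (used for the final refit after
#'   cross-validation).
#' @param epochs Epoch count override; defaults to `config$max_epochs`.
#' @param verbose Print per-epoch progress.
#' @return A `stridenet_model` with the training scaler attached and a
#'   `history` data frame (epoch, train loss/accuracy, validation
#'   loss/accuracy) plus `best_epoch`.
#' @export
train_model <- function(config, train, val = NULL, epochs = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(config, "model_config"), inherits(train, "padded_batch"))
  nb <- dim(train$inputs)[1]
  if (nb == 0) stopf("empty training set")
  epochs <- as.integer(epochs %||% config$max_epochs)
  with_seed(config$seed, {
    model <- init_model(config, input_size = dim(train$inputs)[3])
    model$scaler <- train$scaler
    opt <- adam_init(get_weights(model))
    best <- list(acc = -Inf, w = NULL, epoch = 0L)
    wait <- 0L
    hist <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nb)
      starts <- seq(1, nb, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0; ep_frames <- 0
      for (s in starts) {
        idx <- ord[seq(s, min(s + config$batch_size - 1L, nb))]
        mb <- batch_slice(train, idx)
        B <- length(idx); T <- dim(mb$inputs)[2]
        dm <- make_dropout_masks(config, B, T, config$dropout)
        fw <- train_step(model, mb$inputs, mb$mask, mb$targets,
                         dropout_masks = dm)
        loss <- fw$loss
        st <- adam_step(get_weights(model), fw$grads, opt,
                        lr = config$learning_rate)
        model <- set_weights(model, st$w)
        opt <- st$state
        nfr <- sum(mb$mask)
        ep_loss <- ep_loss + loss * nfr
        ep_correct <- ep_correct +
          masked_accuracy(fw$prob, mb$targets, mb$mask) * nfr
        ep_frames <- ep_frames + nfr
      }
      row <- data.frame(epoch = ep, train_loss = ep_loss / ep_frames,
                        train_accuracy = ep_correct / ep_frames,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(val)) {
        ev <- evaluate_batch(model, val)
        row$val_loss <- ev$loss
        row$val_accuracy <- ev$accuracy
        if (ev$accuracy > best$acc + 1e-12) {
          best <- list(acc = ev$accuracy, w = get_weights(model), epoch = ep)
          wait <- 0L
        } else wait <- wait + 1L
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_acc %s", ep,
                        row$train_loss, row$train_accuracy,
                        ifelse(is.na(row$val_accuracy), "-",
                               sprintf("%.4f", row$val_accuracy))))
      if (!is.null(val) && wait >= config$patience) break
    }
    if (!is.null(val) && !is.null(best$w)) {
      model <- set_weights(model, best$w)
      model$best_epoch <- best$epoch
    } else model$best_epoch <- epochs
    model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    model
  })
}

#' Participant-wise k-fold cross-validation
#'
#' The development protocol: one model per fold, trained on the remaining
#' folds (with that training subset's own scaler, so no leakage) and
#' validated on the held-out fold; masked frame accuracies are reported as
#' mean +/- SD. The best-performing fold's configuration is then retrained
#' on all folds combined — for its own best epoch count, since no
#' validation data remains — to give the final model for testing.
#'
#' @param cycles Labelled [gait_cycle()] list.
#' @param splits Output of [split_participants()].
#' @param config A [model_config()]; fold `k` trains with seed
#'   `config$seed + k`.
#' @param refit Whether to retrain the winning configuration on all folds
#'   (default `TRUE`).
#' @param verbose Print progress.
#' @return A `crossval_result`: `fold_results` data frame, `mean_accuracy`,
#'   `sd_accuracy`, `best_fold`, and `final_model` (when `refit`).
#' @export
cross_validate <- function(cycles, splits, config, refit = TRUE,
                           verbose = FALSE) {
  n_folds <- length(splits$folds)
  if (n_folds < 2) stopf("need at least 2 folds, got %d", n_folds)
  fold_cycles <- lapply(splits$folds, function(p) cycles_for(cycles, p))
  sizes <- vapply(fold_cycles, length, integer(1))
  if (any(sizes == 0)) stopf("fold(s) with no cycles: %s",
                             paste(which(sizes == 0), collapse = ", "))
  res <- vector("list", n_folds)
  models <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr_cycles <- do.call(c, fold_cycles[-k])
    tr <- standardise_and_pad(tr_cycles)
    va <- standardise_and_pad(fold_cycles[[k]], scaler = tr$scaler)
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    if (verbose) message(sprintf("fold %d: %d train / %d val cycles",
                                 k, length(tr_cycles), sizes[k]))
    m <- train_model(cfg_k, tr, va, verbose = verbose)
    ev <- evaluate_batch(m, va)
    models[[k]] <- m
    res[[k]] <- data.frame(fold = k, n_train = length(tr_cycles),
                           n_val = sizes[k], val_accuracy = ev$accuracy,
                           best_epoch = m$best_epoch,
                           epochs_run = nrow(m$history))
  }
  fold_results <- do.call(rbind, res)
  best_fold <- which.max(fold_results$val_accuracy)
  out <- list(fold_results = fold_results,
              mean_accuracy = mean(fold_results$val_accuracy),
              sd_accuracy = sd(fold_results$val_accuracy),
              best_fold = best_fold, final_model = NULL)
  if (refit) {
    all_cycles <- do.call(c, fold_cycles)
    tr <- standardise_and_pad(all_cycles)
    cfg_f <- config
    cfg_f$seed <- config$seed + best_fold
    out$final_model <- train_model(cfg_f, tr, val = NULL,
                                   epochs = fold_results$best_epoch[best_fold],
                                   verbose = verbose)
  }
  class(out) <- "crossval_result"
  out
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval: %d folds, accuracy %.4f +/- %.4f (best fold %d)%s>\n",
              nrow(x$fold_results), x$mean_accuracy, x$sd_accuracy,
              x$best_fold,
              if (is.null(x$final_model)) "" else ", final model refitted"))
  invisible(x)
}
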