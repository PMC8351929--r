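#' Network configuration
#'
#' Architecture and training hyperparameters of the contact classifier:
#' two bidirectional LSTM layers (400 units each), a time-distributed
#' dense layer (200 nodes, ReLU) and a single sigmoid output node, trained
#' with masked binary cross-entropy, Adam, dropout 0.5 after each hidden
#' layer, mini-batches of 200 cycles, at most 100 epochs with early
#' stopping once validation frame accuracy has not improved for 10 epochs.
#' `scaled_down = TRUE` switches to a small profile (2 x 64 units, dense
#' 32) that trains on a single CPU in minutes and is used throughout the
#' package's own tests.
#'
#' @param lstm_layers Number of bidirectional LSTM layers.
#' @param lstm_units Units per direction per LSTM layer.
#' @param dense_units Nodes in the time-distributed dense layer.
#' @param dropout Dropout ratio after each hidden layer, in `[0, 1)`.
#' @param batch_size Mini-batch size in cycles.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs (<= `max_epochs`).
#' @param learning_rate Adam step size (library-default 1e-3).
#' @param seed Integer seed controlling initialisation, shuffling, dropout.
#' @param scaled_down Use the small test profile.
#' @return A `model_config` list.
#' @export
model_config <- function(lstm_layers = 2L, lstm_units = 400L,
                         dense_units = 200L, dropout = 0.5,
                         batch_size = 200L, max_epochs = 100L,
                         patience = 10L, learning_rate = 1e-3,
                         seed = 1L, scaled_down = FALSE) {
  if (isTRUE(scaled_down)) {
    if (missing(lstm_units)) lstm_units <- 64L
    if (missing(dense_units)) dense_units <- 32L
  }
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  if (patience > max_epochs) stopf("patience (%d) exceeds max_epochs (%d)",
                                   patience, max_epochs)
  structure(list(lstm_layers = as.integer(lstm_layers),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 scaled_down = isTRUE(scaled_down)),
            class = "model_config")
}

#' Parameters of a single LSTM cell
#'
#' The raw cell parametrisation: a stacked gate-weight matrix for the
#' forget, input and output gates acting on the concatenation
#' `[h_prev, x]`, plus a separate cell-candidate weight vector, each with
#' a bias. Mostly of didactic and testing value — the batched layer
#' kernels use an equivalent packed layout.
#'
#' @param gate_weights Matrix `3H x (H + F)`, rows stacked forget, input,
#'   output gate blocks.
#' @param gate_bias Length-`3H` bias.
#' @param cell_weights Matrix `H x (H + F)` for the cell candidate.
#' @param cell_bias Length-`H` bias.
#' @return An `lstm_cell_params` list with `hidden_size` and `input_size`.
#' @export
lstm_cell_params <- function(gate_weights, gate_bias, cell_weights,
                             cell_bias) {
  gate_weights <- as.matrix(gate_weights)
  cell_weights <- as.matrix(cell_weights)
  H <- nrow(cell_weights)
  F <- ncol(cell_weights) - H
  if (F < 1 || nrow(gate_weights) != 3L * H ||
      ncol(gate_weights) != H + F ||
      length(gate_bias) != 3L * H || length(cell_bias) != H)
    stopf("inconsistent LSTM cell parameter shapes (hidden %d, input %d)", H, F)
  structure(list(gate_weights = gate_weights, gate_bias = as.numeric(gate_bias),
                 cell_weights = cell_weights, cell_bias = as.numeric(cell_bias),
                 hidden_size = H, input_size = F),
            class = "lstm_cell_params")
}

#' LSTM state
#'
#' @param cell,hidden Numeric vectors `c_t` and `h_t` of equal length. The
#'   hidden state is bounded to `[-1, 1]` elementwise (a sigmoid times a
#'   tanh).
#' @return An `lstm_state` list.
#' @export
lstm_state <- function(cell, hidden) {
  stopifnot(length(cell) == length(hidden))
  structure(list(cell = as.numeric(cell), hidden = as.numeric(hidden)),
            class = "lstm_state")
}

#' One LSTM cell update
#'
#' The cell mathematics in its plainest form: the forget, input and output
#' gates are sigmoids of affine maps of `[h_prev, x]`; the cell state is
#' `c_t = f * c_prev + i * tanh(w_c [h_prev, x] + b_c)`; the output is
#' `h_t = o * tanh(c_t)`.
#'
#' @param params An [lstm_cell_params()].
#' @param state An [lstm_state()] holding `c_prev` and `h_prev`.
#' @param x Input vector at the current time point.
#' @return The updated [lstm_state()].
#' @examples
#' H <- 2; F <- 3
#' p <- lstm_cell_params(matrix(0, 3 * H, H + F), rep(0, 3 * H),
#'                       matrix(0, H, H + F), rep(0, H))
#' s <- lstm_cell_step(p, lstm_state(rep(1, H), rep(0, H)), rep(0, F))
#' s$cell    # 0.5: forget gate sigmoid(0) halves the previous cell state
#' @export
lstm_cell_step <- function(params, state, x) {
  stopifnot(inherits(params, "lstm_cell_params"), inherits(state, "lstm_state"))
  H <- params$hidden_size
  if (length(x) != params$input_size)
    stopf("input length %d != expected %d", length(x), params$input_size)
  if (length(state$hidden) != H)
    stopf("state size %d != hidden size %d", length(state$hidden), H)
  hx <- c(state$hidden, x)
  gates <- 1 / (1 + exp(-(as.numeric(params$gate_weights %*% hx) +
                            params$gate_bias)))
  f <- gates[seq_len(H)]
  i <- gates[H + seq_len(H)]
  o <- gates[2L * H + seq_len(H)]
  g <- tanh(as.numeric(params$cell_weights %*% hx) + params$cell_bias)
  c_t <- f * state$cell + i * g
  lstm_state(c_t, o * tanh(c_t))
}

# pack cell-style parameters into the (H+F) x 4H layer weight layout
# (gate column blocks [forget | input | output | candidate])
pack_cell_params <- function(params) {
  H <- params$hidden_size
  W <- cbind(t(params$gate_weights[seq_len(H), , drop = FALSE]),
             t(params$gate_weights[H + seq_len(H), , drop = FALSE]),
             t(params$gate_weights[2L * H + seq_len(H), , drop = FALSE]),
             t(params$cell_weights))
  list(W = W, b = c(params$gate_bias, params$cell_bias))
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# initialise all weights; forget-gate bias starts at 1 (standard practice,
# keeps early memory open)
init_model <- function(config, input_size = 4L) {
  H <- config$lstm_units
  mk_layer <- function(fin) {
    b <- rep(0, 4 * H)
    b[seq_len(H)] <- 1
    list(W = glorot(fin + H, 4 * H), b = b)
  }
  layers <- list()
  fin <- input_size
  for (l in seq_len(config$lstm_layers)) {
    layers[[sprintf("l%d_fwd", l)]] <- mk_layer(fin)
    layers[[sprintf("l%d_bwd", l)]] <- mk_layer(fin)
    fin <- 2L * H
  }
  structure(list(layers = layers,
                 dense = list(W = glorot(fin, config$dense_units),
                              b = rep(0, config$dense_units)),
                 out = list(W = glorot(config$dense_units, 1L),
                            b = 0),
                 config = config, input_size = as.integer(input_size),
                 scaler = NULL),
            class = "stridenet_model")
}

#' @export
print.stridenet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<stridenet_model: %d x Bi-LSTM(%d) + dense(%d, ReLU) ",
                     "+ sigmoid%s>\n"),
              cfg$lstm_layers, cfg$lstm_units, cfg$dense_units,
              if (is.null(x$scaler)) "" else ", scaler attached"))
  invisible(x)
}

cube_from_inputs <- function(inputs) aperm(inputs, c(1, 3, 2))  # B x F x T

concat_bidir <- function(Hf, Hb) {
  d <- dim(Hf)
  out <- array(0, c(d[1], 2 * d[2], d[3]))
  out[, seq_len(d[2]), ] <- Hf
  out[, d[2] + seq_len(d[2]), ] <- Hb
  out
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# full forward pass. dropout_masks: NULL (inference) or list of arrays with
# the inverted-dropout scaling already applied (one per hidden layer).
model_forward <- function(model, inputs, mask, dropout_masks = NULL,
                          keep_cache = FALSE) {
  B <- dim(inputs)[1]; T <- dim(inputs)[2]
  maskm <- matrix(as.numeric(mask), B, T)
  cfg <- model$config
  X <- cube_from_inputs(inputs)
  cache <- list(X = list(X), lstm = list(), Hcat = list())
  for (l in seq_len(cfg$lstm_layers)) {
    Wf <- model$layers[[sprintf("l%d_fwd", l)]]
    Wb <- model$layers[[sprintf("l%d_bwd", l)]]
    ff <- .lstm_forward_cpp(X, Wf$W, Wf$b, maskm, FALSE)
    bb <- .lstm_forward_cpp(X, Wb$W, Wb$b, maskm, TRUE)
    if (any(!is.finite(ff$H)) || any(!is.finite(bb$H)))
      stopf("non-finite activations in LSTM layer %d", l)
    Hcat <- concat_bidir(ff$H, bb$H)
    if (!is.null(dropout_masks)) Hcat <- Hcat * dropout_masks[[l]]
    cache$lstm[[l]] <- list(fwd = ff, bwd = bb)
    cache$Hcat[[l]] <- Hcat
    X <- Hcat
    cache$X[[l + 1]] <- X
  }
  # time-distributed dense + sigmoid output; rows ordered (cycle, time)
  Hmat <- matrix(aperm(X, c(1, 3, 2)), B * T, dim(X)[2])
  Dpre <- sweep(Hmat %*% model$dense$W, 2, model$dense$b, "+")
  D <- relu(Dpre)
  if (!is.null(dropout_masks)) D <- D * dropout_masks[[cfg$lstm_layers + 1]]
  logits <- as.numeric(D %*% model$out$W) + model$out$b
  prob <- matrix(sigmoid(logits), B, T)
  if (any(!is.finite(prob))) stopf("non-finite activations in output layer")
  out <- list(prob = prob, mask = maskm)
  if (keep_cache)
    out$cache <- c(cache, list(Hmat = Hmat, Dpre = Dpre, D = D, B = B, T = T))
  out
}

#' Predict per-frame contact probabilities
#'
#' Runs the trained network over a padded batch and returns the per-frame
#' probability of ground contact for every cycle. If the batch was not
#' standardised with the model's own training scaler the stored scaler is
#' applied first. Padded positions are never scored; they are reported
#' with their mask so downstream code can ignore them.
#'
#' @param model A trained `stridenet_model` (from [train_model()]).
#' @param batch A `padded_batch` from [standardise_and_pad()].
#' @return A `predicted_contact` object: `probabilities` (cycles x 200),
#'   `mask`, `cycle_ids`, `rate`.
#' @export
predict_contact <- function(model, batch) {
  stopifnot(inherits(model, "stridenet_model"),
            inherits(batch, "padded_batch"))
  fw <- train_step(model, batch$inputs, batch$mask, batch$targets,
                   compute_grads = FALSE)
  structure(list(probabilities = fw$prob, mask = batch$mask,
                 cycle_ids = batch$cycle_ids,
                 rate = batch$meta$rate[1]),
            class = "predicted_contact")
}

#' @export
print.predicted_contact <- function(x, ...) {
  cat(sprintf("<predicted_contact: %d cycles x %d frames @ %g Hz>\n",
              nrow(x$probabilities), ncol(x$probabilities), x$rate))
  invisible(x)
}

#' Masked binary cross-entropy
#'
#' Mean binary cross-entropy over real (unmasked) frames only; padded
#' positions contribute nothing, whatever values they hold.
#'
#' @param prob Matrix of predicted probabilities.
#' @param targets 0/1 matrix of labels.
#' @param mask 0/1 matrix flagging real frames.
#' @return Scalar loss.
#' @export
masked_bce <- function(prob, targets, mask) {
  eps <- 1e-12
  p <- pmin(pmax(prob, eps), 1 - eps)
  ll <- targets * log(p) + (1 - targets) * log(1 - p)
  -sum(ll * mask) / sum(mask)
}

# masked frame classification accuracy
masked_accuracy <- function(prob, targets, mask, threshold = 0.5) {
  sum(((prob >= threshold) == (targets == 1)) * mask) / sum(mask)
}
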