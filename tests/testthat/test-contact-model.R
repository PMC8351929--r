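test_that("the LSTM cell reproduces its closed-form corner cases", {
  H <- 2; F <- 3
  zero <- lstm_cell_params(matrix(0, 3 * H, H + F), rep(0, 3 * H),
                           matrix(0, H, H + F), rep(0, H))
  # all-zero parameters: every gate is sigmoid(0) = 0.5, candidate tanh(0)=0
  s <- lstm_cell_step(zero, lstm_state(rep(0, H), rep(0, H)), rep(0, F))
  expect_equal(s$cell, c(0, 0))
  expect_equal(s$hidden, c(0, 0))
  # with c0 = 1 the forget gate halves it: c1 = 0.5, h1 = 0.5 tanh(0.5)
  s <- lstm_cell_step(zero, lstm_state(rep(1, H), rep(0, H)), rep(0, F))
  expect_equal(s$cell, c(0.5, 0.5))
  expect_equal(s$hidden, rep(0.5 * tanh(0.5), H), tolerance = 1e-12)
  expect_error(lstm_cell_step(zero, lstm_state(rep(0, H), rep(0, H)),
                              rep(0, F + 1)), "input length")
})

test_that("cell steps match the independent scalar-loop oracle", {
  set.seed(11)
  for (r in 1:20) {
    H <- sample(2:5, 1); F <- sample(1:4, 1)
    p <- random_cell_params(H, F)
    st <- lstm_state(rep(0, H), rep(0, H))
    oc <- rep(0, H); oh <- rep(0, H)
    for (t in 1:10) {
      x <- rnorm(F)
      st <- lstm_cell_step(p, st, x)
      o <- oracle_lstm_step(p, oc, oh, x)
      oc <- o$c; oh <- o$h
      expect_lt(max(abs(st$hidden - oh)), 1e-6)
      expect_lt(max(abs(st$cell - oc)), 1e-6)
      expect_true(all(abs(st$hidden) <= 1))
    }
  }
})

test_that("the batched layer kernel matches the scalar oracle", {
  set.seed(13)
  H <- 4; F <- 3; T <- 12; B <- 5
  p <- random_cell_params(H, F)
  packed <- stridenet:::pack_cell_params(p)
  X <- array(rnorm(B * F * T), c(B, F, T))
  fw <- stridenet:::.lstm_forward_cpp(X, packed$W, packed$b,
                                      matrix(1, B, T), FALSE)
  for (b in 1:B) {
    Ho <- oracle_lstm_sequence(p, t(X[b, , ]))
    expect_lt(max(abs(t(fw$H[b, , ]) - Ho)), 1e-6)
  }
  # reversed processing equals the oracle on the flipped sequence
  bw <- stridenet:::.lstm_forward_cpp(X, packed$W, packed$b,
                                      matrix(1, B, T), TRUE)
  for (b in 1:B) {
    Ho <- oracle_lstm_sequence(p, t(X[b, , T:1]))
    expect_lt(max(abs(t(bw$H[b, , T:1]) - Ho)), 1e-6)
  }
})

make_toy_model <- function(H = 3, D = 4, seed = 5, input = 4) {
  cfg <- model_config(lstm_units = H, dense_units = D, dropout = 0,
                      seed = seed)
  stridenet:::with_seed(seed, stridenet:::init_model(cfg, input))
}

test_that("forward pass respects sigmoid bounds and zero-weight symmetry", {
  model <- make_toy_model()
  model <- stridenet:::set_weights(model,
    stridenet:::tree_map(function(x) x * 0, stridenet:::get_weights(model)))
  inputs <- array(rnorm(2 * 6 * 4), c(2, 6, 4))
  mask <- matrix(1, 2, 6)
  fw <- stridenet:::model_forward(model, inputs, mask)
  expect_equal(unname(fw$prob), matrix(0.5, 2, 6))   # sigmoid(0) everywhere

  model2 <- make_toy_model(seed = 9)
  fw2 <- stridenet:::model_forward(model2, inputs, mask)
  expect_true(all(fw2$prob > 0 & fw2$prob < 1))
})

test_that("reversing time and swapping direction weights reverses outputs", {
  H <- 3
  model <- make_toy_model(H = H, seed = 21)
  # swapping the forward/backward units also swaps the two halves of every
  # concatenated output, so downstream weights must be permuted to match
  swapped <- model
  perm <- c(H + seq_len(H), seq_len(H))
  for (l in 1:2) {
    fwd <- sprintf("l%d_fwd", l); bwd <- sprintf("l%d_bwd", l)
    swapped$layers[[fwd]] <- model$layers[[bwd]]
    swapped$layers[[bwd]] <- model$layers[[fwd]]
  }
  for (nm in c("l2_fwd", "l2_bwd")) {
    W <- swapped$layers[[nm]]$W
    W[H + seq_len(2 * H), ] <- W[H + perm, ]   # x-part rows follow the swap
    swapped$layers[[nm]]$W <- W
  }
  swapped$dense$W <- swapped$dense$W[perm, ]
  B <- 3; T <- 9
  inputs <- array(rnorm(B * T * 4), c(B, T, 4))
  mask <- matrix(1, B, T)
  fw <- stridenet:::model_forward(model, inputs, mask)
  rev_inputs <- inputs[, T:1, , drop = FALSE]
  fw_rev <- stridenet:::model_forward(swapped, rev_inputs, mask)
  expect_equal(fw_rev$prob[, T:1], fw$prob, tolerance = 1e-12)
})

test_that("fused training step equals the reference R path exactly", {
  set.seed(31)
  cfg <- model_config(lstm_units = 3, dense_units = 4, dropout = 0.3,
                      seed = 8)
  model <- stridenet:::with_seed(8, stridenet:::init_model(cfg, 4))
  B <- 4; T <- 11
  inputs <- array(rnorm(B * T * 4), c(B, T, 4))
  mask <- matrix(1, B, T); mask[1, 1:4] <- 0; inputs[1, 1:4, ] <- 0
  targets <- matrix(rbinom(B * T, 1, 0.5), B, T)
  dm <- stridenet:::with_seed(3, stridenet:::make_dropout_masks(cfg, B, T,
                                                                cfg$dropout))
  fwR <- stridenet:::model_forward(model, inputs, mask, dropout_masks = dm,
                                   keep_cache = TRUE)
  grR <- stridenet:::model_backward(model, fwR, targets, dropout_masks = dm)
  st <- stridenet:::train_step(model, inputs, mask, targets,
                               dropout_masks = dm)
  expect_equal(st$loss, masked_bce(fwR$prob, targets, mask),
               tolerance = 1e-14)
  expect_equal(st$prob, fwR$prob, tolerance = 1e-14)
  diffs <- unlist(stridenet:::tree_map2(function(a, b) max(abs(a - b)),
                                        grR, st$grads))
  scale <- unlist(stridenet:::tree_map(function(x) max(abs(x), 1e-9),
                                       grR))
  expect_lt(max(diffs / scale), 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(41)
  model <- make_toy_model(H = 3, D = 3, seed = 14)
  B <- 3; T <- 8
  inputs <- array(rnorm(B * T * 4), c(B, T, 4))
  mask <- matrix(1, B, T); mask[2, 1:5] <- 0; inputs[2, 1:5, ] <- 0
  targets <- matrix(rbinom(B * T, 1, 0.5), B, T)
  st <- stridenet:::train_step(model, inputs, mask, targets)
  loss_at <- function(m)
    stridenet:::train_step(m, inputs, mask, targets,
                           compute_grads = FALSE)$loss
  eps <- 1e-6
  for (nm in names(model$layers)) {
    w <- model$layers[[nm]]$W
    for (j in sample(length(w), 8)) {
      m1 <- model; m1$layers[[nm]]$W[j] <- w[j] + eps
      m2 <- model; m2$layers[[nm]]$W[j] <- w[j] - eps
      num <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
      expect_equal(st$grads$layers[[nm]]$W[j], num, tolerance = 1e-5)
    }
  }
})

test_that("losses and metrics ignore padded positions entirely", {
  set.seed(51)
  model <- make_toy_model(seed = 3)
  B <- 4; T <- 10
  inputs <- array(rnorm(B * T * 4), c(B, T, 4))
  mask <- matrix(1, B, T)
  for (b in 1:B) {
    pad <- sample(0:4, 1)
    if (pad > 0) { mask[b, seq_len(pad)] <- 0; inputs[b, seq_len(pad), ] <- 0 }
  }
  targets <- matrix(rbinom(B * T, 1, 0.5), B, T)
  ref <- stridenet:::train_step(model, inputs, mask, targets)
  pert <- inputs
  for (b in 1:B) {
    pad <- sum(mask[b, ] == 0)
    if (pad > 0) pert[b, seq_len(pad), ] <- rnorm(pad * 4, sd = 50)
  }
  got <- stridenet:::train_step(model, pert, mask, targets)
  expect_identical(got$loss, ref$loss)
  expect_identical(stridenet:::masked_accuracy(got$prob, targets, mask),
                   stridenet:::masked_accuracy(ref$prob, targets, mask))
  gd <- unlist(stridenet:::tree_map2(function(a, b) max(abs(a - b)),
                                     ref$grads, got$grads))
  expect_true(all(gd == 0))
})

test_that("training is seeded, overfits separable data, and stops early", {
  cycles <- label_cycles(generate_dataset(tiny_config(2, 13, seed = 61)))
  tr <- standardise_and_pad(cycles[1:20])
  va <- standardise_and_pad(cycles[21:26], scaler = tr$scaler)
  cfg <- model_config(lstm_units = 16, dense_units = 8, dropout = 0,
                      batch_size = 20, max_epochs = 250, patience = 250,
                      learning_rate = 5e-3, seed = 71)
  m1 <- train_model(cfg, tr, va)
  # clean phase-locked cycles are separable: training accuracy reaches 100%
  expect_equal(max(m1$history$train_accuracy), 1)
  m2 <- train_model(cfg, tr, va)
  expect_identical(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_identical(m1$history$train_loss, m2$history$train_loss)

  # with a zero learning rate validation accuracy never improves after the
  # first epoch, so patience p stops training at epoch p + 1
  cfg0 <- model_config(lstm_units = 8, dense_units = 4, dropout = 0,
                       batch_size = 20, max_epochs = 20, patience = 3,
                       learning_rate = 0, seed = 72)
  m0 <- train_model(cfg0, tr, va)
  expect_equal(nrow(m0$history), 4)
  empty <- tr
  empty$inputs <- tr$inputs[0, , , drop = FALSE]
  expect_error(train_model(cfg, empty, va), "empty training set")
})

test_that("cross-validation reports per-fold accuracy and refits on all folds", {
  cycles <- label_cycles(generate_dataset(tiny_config(4, 8, seed = 81)))
  splits <- list(folds = list(c("P01", "P02"), c("P03", "P04")))
  cfg <- model_config(lstm_units = 8, dense_units = 4, dropout = 0,
                      batch_size = 16, max_epochs = 30, patience = 30,
                      learning_rate = 3e-3, seed = 91)
  cv <- cross_validate(cycles, splits, cfg)
  expect_equal(nrow(cv$fold_results), 2)
  expect_true(all(cv$fold_results$val_accuracy > 0.8))
  expect_equal(cv$mean_accuracy, mean(cv$fold_results$val_accuracy))
  expect_equal(cv$sd_accuracy, sd(cv$fold_results$val_accuracy))
  # the final model is trained on every fold's cycles combined
  expect_equal(cv$final_model$history$epoch[1], 1)
  expect_s3_class(cv$final_model, "stridenet_model")
  expect_identical(
    length(cycles_for(cycles, unlist(splits$folds))),
    length(cycles))
  expect_error(cross_validate(cycles, list(folds = list("P01")), cfg),
               "at least 2")
})
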