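# Independent reference implementations used as oracles. These are written
# as plain scalar loops, deliberately sharing no code with the package.

# one LSTM cell update, unit by unit, directly from the gate equations
oracle_lstm_step <- function(params, c_prev, h_prev, x) {
  H <- params$hidden_size
  hx <- c(h_prev, x)
  f <- i <- o <- g <- numeric(H)
  for (j in seq_len(H)) {
    sf <- params$gate_bias[j]
    si <- params$gate_bias[H + j]
    so <- params$gate_bias[2 * H + j]
    sg <- params$cell_bias[j]
    for (k in seq_along(hx)) {
      sf <- sf + params$gate_weights[j, k] * hx[k]
      si <- si + params$gate_weights[H + j, k] * hx[k]
      so <- so + params$gate_weights[2 * H + j, k] * hx[k]
      sg <- sg + params$cell_weights[j, k] * hx[k]
    }
    f[j] <- 1 / (1 + exp(-sf))
    i[j] <- 1 / (1 + exp(-si))
    o[j] <- 1 / (1 + exp(-so))
    g[j] <- tanh(sg)
  }
  cc <- f * c_prev + i * g
  list(c = cc, h = o * tanh(cc))
}

# run a whole sequence through the scalar cell oracle
oracle_lstm_sequence <- function(params, X) {      # X: T x F
  H <- params$hidden_size
  st <- list(c = rep(0, H), h = rep(0, H))
  t(vapply(seq_len(nrow(X)), function(t) {
    st <<- oracle_lstm_step(params, st$c, st$h, X[t, ])
    st$h
  }, numeric(H)))
}

# brute-force unloading-rate check: locate the last fall through 100 N and
# the next fall below 50 N by scanning, then test every consecutive pair
oracle_qc_accept <- function(f, rate, max_rate = 200) {
  a <- NA
  for (i in seq_len(length(f) - 1))
    if (f[i] >= 100 && f[i + 1] < 100) a <- i
  if (is.na(a)) return(TRUE)
  b <- length(f)
  for (j in (a + 1):length(f)) {
    if (f[j] < 50) { b <- j; break }
  }
  for (k in a:(b - 1))
    if ((f[k + 1] - f[k]) * rate >= max_rate) return(FALSE)
  TRUE
}

# longest run of values >= threshold by exhaustive enumeration of all
# contiguous runs; first run wins ties; returns c(start, end) 1-based
oracle_longest_run <- function(p, threshold) {
  best <- NULL
  s <- 1
  while (s <= length(p)) {
    if (p[s] >= threshold) {
      e <- s
      while (e < length(p) && p[e + 1] >= threshold) e <- e + 1
      if (is.null(best) || (e - s) > (best[2] - best[1])) best <- c(s, e)
      s <- e + 1
    } else s <- s + 1
  }
  best
}

oracle_rmse <- function(e) {
  s <- 0
  for (v in e) s <- s + v * v
  sqrt(s / length(e))
}

# linear-interpolation percentile (quantile type 7) from first principles
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

oracle_frame_accuracy <- function(prob, targets, mask, threshold = 0.5) {
  hit <- 0; tot <- 0
  for (u in seq_along(prob)) {
    if (mask[u] == 1) {
      tot <- tot + 1
      if ((prob[u] >= threshold) == (targets[u] == 1)) hit <- hit + 1
    }
  }
  hit / tot
}

# small noise-free generator setup shared across tests
tiny_config <- function(n_participants = 3, cycles_per_participant = 5,
                        seed = 42, ...) {
  synthetic_config(n_participants = n_participants,
                   cycles_per_participant = cycles_per_participant,
                   noise_sd = 0, qc_violation_rate = 0, seed = seed, ...)
}

random_cell_params <- function(H, F, sd = 0.4) {
  lstm_cell_params(matrix(rnorm(3 * H * (H + F), sd = sd), 3 * H, H + F),
                   rnorm(3 * H, sd = 0.2),
                   matrix(rnorm(H * (H + F), sd = sd), H, H + F),
                   rnorm(H, sd = 0.2))
}

# events implied by a synthetic truth record, mapped to the nearest mocap
# frame with the same round-half-up convention the pipeline documents
truth_events_of <- function(cycle) {
  tr <- cycle$truth
  data.frame(fs = as.integer(tr$contact_start_time * cycle$rate + 0.5),
             to = as.integer(tr$contact_end_time * cycle$rate + 0.5))
}
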