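test_that("trials segment at foot-COM apices with known boundaries", {
  cycles <- generate_dataset(tiny_config(1, 5, seed = 12))
  trial <- concatenate_cycles(cycles)
  seg <- segment_cycles(trial$foot_vert_pos, trial$channels)
  expect_equal(length(seg$cycles), 4)            # 5 apices bound 4 cycles
  true_lens <- vapply(cycles, function(cy) nrow(cy$features), integer(1))
  seg_lens <- vapply(seg$cycles, function(s) length(s$foot_vert_pos$values),
                     integer(1))
  expect_true(all(abs(seg_lens - true_lens[1:4]) <= 1))
  # channels are carved alongside the position signal
  expect_equal(seg$cycles[[1]]$ankle_angle$values,
               trial$channels$ankle_angle$values[
                 seg$apices[1]:(seg$apices[2] - 1)])
})

test_that("degenerate trials yield no cycles, plateaus break first", {
  mono <- time_series(seq(0, 1, length.out = 300), 100)
  expect_warning(res <- segment_cycles(mono), "fewer than 2")
  expect_length(res$cycles, 0)

  # two equal maxima form a plateau: the boundary is its first index
  v <- c(0, 1, 3, 3, 1, 0, 1, 3, 1, 0)
  p <- time_series(rep(v, 2), 100)
  seg <- segment_cycles(p, min_separation = 0)
  expect_equal(seg$apices[1], 3)
})

test_that("the 200 N/s unloading rule matches its stated boundary cases", {
  descent <- function(bump) {
    f <- c(400, 300, 200, 150, 120, 100, 90, 80, 70, 60, 55, 45, 20, 0)
    if (!is.na(bump)) f <- append(f, f[9] + bump, after = 9)
    time_series(f, 200)
  }
  expect_true(qc_filter(descent(NA))$accepted)         # monotone drop
  expect_false(qc_filter(descent(1.0))$accepted)       # 1 N/frame @200 Hz
  expect_true(qc_filter(descent(0.9))$accepted)        # 180 N/s < 200 N/s
  low <- time_series(c(0, 40, 80, 90, 80, 40, 0), 200)
  q <- qc_filter(low)
  expect_true(q$accepted)
  expect_match(q$reason, "interval absent")
})

test_that("the rule only inspects the terminal 100 to 50 N drop", {
  # a rise during loading or mid-stance is not a violation
  f <- time_series(c(0, 60, 55, 300, 800, 700, 900, 400, 120, 90, 60, 40, 0),
                   200)
  expect_true(qc_filter(f)$accepted)
})

test_that("qc_filter agrees with the brute-force oracle on random traces", {
  set.seed(301)
  for (r in 1:200) {
    n <- sample(30:80, 1)
    f <- seq(sample(150:400, 1), 0, length.out = n) +
      c(0, cumsum(rnorm(n - 1, 0, 0.4)))
    f <- pmax(f, 0)
    if (runif(1) < 0.5) {                        # inject an aberrant bump
      j <- sample(seq(5, n - 5), 1)
      f[j] <- f[j] + runif(1, 0.1, 3)
    }
    ts <- time_series(f, 200)
    expect_identical(qc_filter(ts)$accepted, oracle_qc_accept(f, 200),
                     info = sprintf("trace %d", r))
  }
})

test_that("contact labelling thresholds at exactly 50 N", {
  cy <- gait_cycle(matrix(rnorm(20), 5, 4), rate = 100,
                   vgrf = time_series(c(0, 60, 120, 60, 0), 100),
                   cycle_id = "t1")
  cy <- label_contact(cy)
  expect_identical(cy$labels, c(0L, 1L, 1L, 1L, 0L))
  expect_equal(cy$events$foot_strike_index, 1)
  expect_equal(cy$events$toe_off_index, 3)

  at50 <- gait_cycle(matrix(rnorm(20), 5, 4), rate = 100,
                     vgrf = time_series(c(0, 50, 120, 49.999, 0), 100))
  at50 <- label_contact(at50)
  expect_identical(at50$labels, c(0L, 1L, 1L, 0L, 0L))

  none <- gait_cycle(matrix(rnorm(20), 5, 4), rate = 100,
                     vgrf = time_series(c(0, 10, 20, 10, 0), 100))
  expect_error(label_contact(none), "no contact")
})

test_that("force frames map to the nearest mocap frame, round-half-up", {
  # first contact at force frame 103 of a 1000 Hz trace = 0.103 s,
  # which is closest to mocap frame 21 (0.105 s) at 200 Hz
  n_force <- 800
  f <- numeric(n_force)
  f[104:600] <- 100                              # frames 103..599, 0-based
  cy <- gait_cycle(matrix(rnorm(160 * 4), 160, 4), rate = 200,
                   vgrf = time_series(f, 1000))
  cy <- label_contact(cy)
  expect_equal(cy$events$foot_strike_index, 21)
  expect_equal(cy$events$toe_off_index, 120)     # 0.599 s -> 119.8 -> 120
})

test_that("multiple thresholded runs keep the longest with a warning", {
  f <- numeric(60)
  f[5:6] <- 55                                   # spurious 2-frame run
  f[20:50] <- 300
  cy <- gait_cycle(matrix(rnorm(240), 60, 4), rate = 100,
                   vgrf = time_series(f, 100), cycle_id = "w1")
  expect_warning(cy <- label_contact(cy), "keeping the longest")
  expect_equal(cy$events$foot_strike_index, 19)
  expect_equal(cy$events$toe_off_index, 49)
})

test_that("standardise_and_pad z-scores with the training scaler only", {
  cycles <- label_cycles(generate_dataset(tiny_config(3, 6, seed = 7)))
  batch <- standardise_and_pad(cycles)
  real <- batch$mask == 1
  for (ch in 1:4) {
    v <- batch$inputs[, , ch][real]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sd(v), 1, tolerance = 1e-9)
  }
  # padded positions are exact zeros; mask row sums are the cycle lengths
  expect_true(all(batch$inputs[!real] == 0))
  expect_identical(as.integer(rowSums(batch$mask)),
                   as.integer(batch$lengths))
  # padding is prepended: a 140-sample cycle occupies rows 61..200
  i <- which(batch$lengths == batch$lengths[1])[1]
  expect_true(all(batch$mask[i, seq_len(200 - batch$lengths[i])] == 0))
  expect_true(all(batch$mask[i, (200 - batch$lengths[i] + 1):200] == 1))

  # a held-out batch reuses the training scaler verbatim
  other <- standardise_and_pad(cycles[1:3], scaler = batch$scaler)
  expect_identical(other$scaler, batch$scaler)
})

test_that("degenerate channels and over-long cycles are rejected", {
  cy <- generate_dataset(tiny_config(1, 2, seed = 2))
  cy[[1]]$features[, "ankle_angle"] <- 5
  cy[[2]]$features[, "ankle_angle"] <- 5
  expect_error(standardise_and_pad(cy), "degenerate channel")
  expect_error(standardise_and_pad(generate_dataset(tiny_config(1, 2)),
                                   max_len = 100), "longer than 100")
})

test_that("participant splits partition every participant exactly once", {
  cfg <- synthetic_config(n_participants = 20, cycles_per_participant = 2,
                          n_datasets = 2, seed = 17)
  cycles <- generate_dataset(cfg)
  sp <- split_participants(cycles, test_fraction = 0.3, n_folds = 5,
                           seed = 1)
  expect_length(sp$test, 6)                      # 3 of 10 per dataset
  all_ids <- sort(unique(cycle_metadata(cycles)$participant_id))
  assigned <- c(sp$test, unlist(sp$folds))
  expect_identical(sort(assigned), all_ids)      # no overlap, no omission
  expect_identical(anyDuplicated(assigned), 0L)
  # stratification: each partition draws from both datasets
  meta <- unique(cycle_metadata(cycles)[, c("participant_id", "dataset_id")])
  ds_of <- function(p) meta$dataset_id[match(p, meta$participant_id)]
  expect_setequal(unique(ds_of(sp$test)), c("D1", "D2"))
  # determinism
  expect_identical(sp$assignment,
                   split_participants(cycles, 0.3, 5, seed = 1)$assignment)
  expect_error(split_participants(cycles, 0.3, 8, seed = 1), "fewer than")
})
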