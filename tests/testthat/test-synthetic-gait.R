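test_that("config invariants are enforced", {
  expect_error(synthetic_config(strike_mix = c(0.5, 0.4, 0.2)), "sum")
  expect_error(synthetic_config(force_rate = 500, mocap_rate = 150),
               "integer multiple")
  expect_error(synthetic_config(qc_violation_rate = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_cycle_truth(0.5, 0.3, 0.8, 3), "contact_start")
  expect_error(synthetic_cycle_truth(0.1, 0.2, 0.8, 3), "duty factor")
})

test_that("cycle geometry follows the committed truth", {
  cfg <- tiny_config()
  tr <- synthetic_cycle_truth(0.14, 0.14 + 0.35 * 0.7, 0.7, speed = 3.5)
  cy <- generate_cycle(cfg, tr, noise = FALSE)
  expect_equal(nrow(cy$features), 140)           # 0.7 s at 200 Hz
  cy <- label_contact(cy)
  # duty factor 0.35 of 140 mocap frames: 49 frames between the events
  expect_equal(cy$events$toe_off_index - cy$events$foot_strike_index, 49)
  expect_error(
    generate_cycle(cfg, synthetic_cycle_truth(0.3, 0.7, 1.2, speed = 2)),
    "200-sample")
})

test_that("noise-free vGRF thresholding recovers truth exactly", {
  cycles <- label_cycles(generate_dataset(tiny_config(4, 8)))
  for (cy in cycles) {
    tru <- truth_events_of(cy)
    expect_identical(cy$events$foot_strike_index, tru$fs)
    expect_identical(cy$events$toe_off_index, tru$to)
    # one contiguous contact run in the labels
    expect_identical(sum(abs(diff(cy$labels))), 2L)
  }
})

test_that("strike patterns shape the ankle angle at contact", {
  cfg <- tiny_config()
  mk <- function(pattern, fsa) {
    tr <- synthetic_cycle_truth(0.15, 0.40, 0.72, 3, strike_pattern = pattern,
                                foot_strike_angle = fsa)
    cy <- label_contact(generate_cycle(cfg, tr, noise = FALSE))
    cy$features[cy$events$foot_strike_index + 1, "ankle_angle"]
  }
  expect_gt(mk("rearfoot", 14), 5)
  expect_lt(mk("forefoot", -12), -5)
})

test_that("generation is deterministic and respects the configured mix", {
  cfg <- synthetic_config(n_participants = 10, cycles_per_participant = 4,
                          qc_violation_rate = 0.1, seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)

  meta <- cycle_metadata(a)
  expect_equal(nrow(meta), 40)
  expect_equal(length(unique(meta$participant_id)), 10)
  by_p <- unique(meta[, c("participant_id", "strike_pattern")])
  expect_equal(nrow(by_p), 10)                   # constant per participant
  expect_equal(sum(by_p$strike_pattern == "rearfoot"), 6)
  expect_equal(sum(by_p$strike_pattern == "midfoot"), 2)
  expect_equal(sum(by_p$strike_pattern == "forefoot"), 2)

  flags <- vapply(a, function(cy) cy$truth$has_qc_violation, logical(1))
  expect_identical(sum(flags),
                   sum(vapply(b, function(cy) cy$truth$has_qc_violation,
                              logical(1))))
})

test_that("injected QC violations are caught by the filter", {
  cfg <- synthetic_config(n_participants = 3, cycles_per_participant = 10,
                          noise_sd = 0, qc_violation_rate = 1, seed = 5)
  cycles <- qc_filter_cycles(generate_dataset(cfg))
  expect_true(all(!vapply(cycles, `[[`, logical(1), "accepted")))
  clean <- qc_filter_cycles(generate_dataset(tiny_config(3, 10)))
  expect_true(all(vapply(clean, `[[`, logical(1), "accepted")))
})

test_that("waveform invariants hold before noise", {
  cycles <- generate_dataset(tiny_config(3, 6, seed = 8))
  for (cy in cycles) {
    expect_true(all(is.finite(cy$features)))
    expect_true(all(cy$vgrf$values >= 0))
    vv <- cy$features[, "foot_vert_vel"]
    expect_lt(abs(mean(vv)), 1e-6 * max(abs(vv)))
  }
})

test_that("speed modulates cycle duration and duty factor inversely", {
  cycles <- generate_dataset(synthetic_config(n_participants = 8,
                                              cycles_per_participant = 20,
                                              seed = 31))
  meta <- cycle_metadata(cycles)
  duty <- vapply(cycles, function(cy)
    (cy$truth$contact_end_time - cy$truth$contact_start_time) /
      cy$truth$duration, numeric(1))
  dur <- vapply(cycles, function(cy) cy$truth$duration, numeric(1))
  expect_lt(cor(meta$speed, dur), -0.8)
  expect_lt(cor(meta$speed, duty), -0.8)
  expect_true(all(duty >= 0.2 & duty <= 0.5))
})
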