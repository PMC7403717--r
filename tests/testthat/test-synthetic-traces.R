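test_that("full ratchet yields a non-increasing staircase, zero ratchet returns to baseline", {
  p1 <- pulse_trace_params(ratchet_efficiency = 1, noise_sd_um2 = 0)
  tr1 <- gen_pulse_trace(p1)
  expect_true(all(diff(tr1$area_um2) <= 1e-12))

  p0 <- pulse_trace_params(ratchet_efficiency = 0, noise_sd_um2 = 0)
  tr0 <- gen_pulse_trace(p0)
  n <- length(tr0$area_um2)
  # first and last plateau sit at the initial area
  expect_equal(tr0$area_um2[1], p0$initial_area_um2)
  expect_equal(tr0$area_um2[n], p0$initial_area_um2)
})

test_that("conservation: total retained loss equals k * e * amplitude exactly", {
  for (e in c(0, 0.25, 0.5, 0.75, 1)) {
    p <- pulse_trace_params(duration_s = 38 + 10 * 76 + 38, ratchet_efficiency = e,
                            pulse_amplitude_um2 = 4, noise_sd_um2 = 0)
    tr <- gen_pulse_trace(p)
    gt <- attr(tr, "ground_truth")
    expect_length(gt$pulse_onset_s, 10)
    expect_equal(tr$area_um2[length(tr$area_um2)], 41 - 10 * e * 4, tolerance = 1e-12)
  }
})

test_that("reporter intensity rises during constriction and never decreases", {
  tr <- gen_pulse_trace(pulse_trace_params(reporter_gain = 2))
  expect_true(all(diff(tr$intensity) >= 0))
  gt <- attr(tr, "ground_truth")
  # strictly rising across each constriction phase
  i0 <- which.min(abs(tr$times_s - gt$pulse_onset_s[1]))
  i1 <- which.min(abs(tr$times_s - gt$area_min_s[1]))
  expect_gt(tr$intensity[i1], tr$intensity[i0])
})

test_that("traces are bit-identical for a fixed seed and differ across seeds", {
  p <- pulse_trace_params(noise_sd_um2 = 0.5, seed = 11)
  expect_identical(gen_pulse_trace(p), gen_pulse_trace(p))
  p2 <- pulse_trace_params(noise_sd_um2 = 0.5, seed = 12)
  expect_false(identical(gen_pulse_trace(p)$area_um2, gen_pulse_trace(p2)$area_um2))
})

test_that("invalid parameter sets are rejected", {
  expect_error(pulse_trace_params(dt_s = 0), class = "ap_invalid_parameters")
  expect_error(pulse_trace_params(duration_s = 10), class = "ap_invalid_parameters")
  expect_error(pulse_trace_params(ratchet_efficiency = 1.2), class = "ap_invalid_parameters")
  # amplitude larger than the cell drives area <= 0
  expect_error(gen_pulse_trace(pulse_trace_params(pulse_amplitude_um2 = 60)),
               class = "ap_invalid_parameters")
})

test_that("largest-remainder class assignment reproduces printed mixes exactly", {
  expect_identical(largest_remainder_counts(300, c(0.50, 0.44, 0.06)),
                   c(150L, 132L, 18L))
  expect_identical(largest_remainder_counts(7, c(1, 0, 0)), c(7L, 0L, 0L))
  # remainders distributed so the total is always exact
  for (n in c(3, 10, 101)) {
    cts <- largest_remainder_counts(n, c(0.91, 0.06, 0.03))
    expect_equal(sum(cts), n)
  }
})

test_that("gen_cohort labels follow the mix and are seed-reproducible", {
  cp <- cohort_params(n_cells = 50, class_mix = c(constricted = 1, impaired = 0, expanded = 0),
                      seed = 5)
  co <- gen_cohort(cp)
  expect_s3_class(co, "trace_cohort")
  expect_true(all(attr(co, "truth")$class == "constricted"))
  expect_identical(gen_cohort(cp), gen_cohort(cp))
})

test_that("cohort traces reproduce their drawn target peak rates through the pipeline", {
  co <- gen_cohort(cohort_params(n_cells = 25, class_mix = c(0, 1, 0), seed = 9))
  tru <- attr(co, "truth")
  cr <- vapply(co, mean_peak_rate, numeric(1), polarity = "constriction")
  er <- vapply(co, mean_peak_rate, numeric(1), polarity = "expansion")
  expect_equal(cr, tru$target_constriction_rate, tolerance = 1e-8,
               ignore_attr = TRUE)
  # expansion targets below the waveform's slowest achievable relaxation are
  # clipped upward, so rare cells exceed their draw; the rest are exact
  expect_gte(mean(abs(er - tru$target_expansion_rate) < 1e-6), 0.8)
  expect_lt(abs(mean(er) - 5.1), 0.3)
})
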