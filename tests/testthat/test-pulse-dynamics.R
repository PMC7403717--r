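test_that("gap interpolation fills short interior runs and trims edges", {
  tr <- mk_trace(c(4, NA, 2))
  expect_equal(interpolate_gaps(tr)$area_um2, c(4, 3, 2))

  # a run of three missing is not "smaller than three time points"
  tr3 <- mk_trace(c(5, 4, NA, NA, NA, 2, 3))
  out3 <- interpolate_gaps(tr3)
  expect_equal(is.na(out3$area_um2), c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # ... but a run of two is interpolated
  tr2 <- mk_trace(c(5, 4, NA, NA, 1, 3))
  expect_false(anyNA(interpolate_gaps(tr2)$area_um2))

  trim <- interpolate_gaps(mk_trace(c(NA, 5, 6)))
  expect_equal(trim$area_um2, c(5, 6))
  expect_equal(trim$times_s, c(3.8, 7.6))

  expect_error(interpolate_gaps(mk_trace(c(NA, NA, NA))), class = "ap_empty_trace")
})

test_that("moving mean matches the brute-force oracle and handles edge cases", {
  x <- c(5, 1, 4, 4, 2, 8)
  expect_equal(smooth_moving_mean(x, 1), x)
  expect_equal(smooth_moving_mean(rep(3, 10), 5), rep(3, 10))
  set.seed(1)
  for (i in 1:50) {
    x <- rnorm(sample(7:40, 1))
    w <- sample(c(3, 5, 7), 1)
    expect_equal(smooth_moving_mean(x, w), oracle_moving_mean(x, w))
  }
  expect_error(smooth_moving_mean(numeric(0), 3), class = "ap_empty_input")
})

test_that("constriction rate of a linear ramp is the negated slope in um^2/min", {
  # area falling 10 um^2/min = 10/60 um^2/s
  tr <- mk_trace(40 - (0:20) * 3.8 * 10 / 60)
  r <- constriction_rate(tr, smooth_window = 1)
  expect_equal(r$rate_um2_per_min, rep(10, 20), tolerance = 1e-12)
  expect_equal(r$times_s, (0:19) * 3.8 + 1.9)

  expect_equal(constriction_rate(mk_trace(rep(30, 10)), smooth_window = 1)$rate_um2_per_min,
               rep(0, 9))
  # rising area gives negative constriction rate
  tr_up <- mk_trace(30 + (0:10) * 3.8 * 5 / 60)
  expect_equal(constriction_rate(tr_up, smooth_window = 1)$rate_um2_per_min,
               rep(-5, 10), tolerance = 1e-12)
  expect_error(constriction_rate(mk_trace(c(10, NA, NA))), class = "ap_too_short")
})

test_that("cubic detrending reconstructs the input and isolates oscillations", {
  t <- (0:60) * 3.8
  cubic <- 40 - 0.02 * t + 1e-5 * t^2 - 1e-8 * t^3
  d <- detrend_area(mk_trace(cubic))
  expect_lt(max(abs(d$residual_um2)), 1e-9)
  expect_equal(d$residual_um2 + d$trend_um2, cubic, tolerance = 1e-12)

  dconst <- detrend_area(mk_trace(rep(25, 10)))
  expect_equal(dconst$residual_um2, rep(0, 10), tolerance = 1e-9)

  # cubic + sinusoid: residual equals sinusoid minus its own best cubic fit
  wave <- 2 * sin(2 * pi * t / 76)
  d2 <- detrend_area(mk_trace(cubic + wave))
  fit <- lm(wave ~ poly(t, 3, raw = TRUE))
  expect_equal(d2$residual_um2, unname(residuals(fit)), tolerance = 1e-8)
})

test_that("detrend-then-reconstruct is the identity on generated traces", {
  for (s in 1:5) {
    tr <- gen_pulse_trace(pulse_trace_params(noise_sd_um2 = 0.4, seed = s,
                                             trend_coeffs = c(0, -0.02, 1e-5, 0)))
    d <- detrend_area(tr)
    expect_equal(d$residual_um2 + d$trend_um2, tr$area_um2, tolerance = 1e-9)
  }
})

test_that("category boundaries follow the (<0.5; 0.5<=r<=1; >1) convention", {
  ramp_to <- function(ratio) {
    n <- 120
    mk_trace(seq(40, 40 * ratio, length.out = n))  # covers 420 s at dt 3.8
  }
  expect_equal(as.character(categorize_cell(ramp_to(0.4))$label), "constricted")
  expect_equal(as.character(categorize_cell(ramp_to(0.7))$label), "impaired")
  expect_equal(as.character(categorize_cell(ramp_to(1.2))$label), "expanded")
  # exact boundary ratios land in "impaired"
  expect_equal(as.character(categorize_cell(mk_trace(rep(40, 120)))$label), "impaired")
  half <- categorize_cell(ramp_to(0.5))
  expect_equal(as.character(half$label), "impaired")
  expect_error(categorize_cell(mk_trace(rep(40, 20))), class = "ap_untracked_at_eval")
})

test_that("short-track exclusion removes cells far below the median duration", {
  mk_cells <- function(lens) {
    as_cohort <- lapply(seq_along(lens), function(i)
      mk_trace(rep(30, lens[i]), cell_id = paste0("c", i)))
    structure(as_cohort, class = "trace_cohort")
  }
  eq <- exclude_short_tracks(mk_cells(rep(50, 8)))
  expect_equal(sum(eq$report$excluded), 0)

  mixed <- exclude_short_tracks(mk_cells(c(rep(80, 100), 4)))
  expect_equal(sum(mixed$report$excluded), 1)
  expect_true(mixed$report$excluded[101])
  expect_length(mixed$cohort, 100)

  empty <- exclude_short_tracks(structure(list(), class = "trace_cohort"))
  expect_length(empty$cohort, 0)
})

test_that("two-stage per-embryo averaging matches a brute-force oracle", {
  one <- structure(list(
    mk_trace(c(2, 2), embryo_id = "A", cell_id = "c1"),
    mk_trace(c(4, 4), embryo_id = "A", cell_id = "c2")), class = "trace_cohort")
  s1 <- per_embryo_average(one)$summary
  expect_equal(s1$mean, c(3, 3))
  expect_equal(s1$sd, c(0, 0))

  two <- structure(list(
    mk_trace(c(3, 3), embryo_id = "A"), mk_trace(c(5, 5), embryo_id = "B")),
    class = "trace_cohort")
  s2 <- per_embryo_average(two)$summary
  expect_equal(s2$mean, c(4, 4))
  expect_equal(s2$sd, rep(sqrt(2), 2))

  # random cohort vs direct two-stage computation
  co <- gen_cohort(cohort_params(n_cells = 12, n_embryos = 3, seed = 4))
  res <- per_embryo_average(co)
  t0 <- res$summary$time_s[5]
  emb_means <- sapply(c("emb1", "emb2", "emb3"), function(e) {
    vals <- sapply(co, function(tr)
      if (tr$embryo_id == e) tr$area_um2[which(abs(tr$times_s - t0) < 1e-6)] else NA)
    mean(unlist(vals), na.rm = TRUE)
  })
  expect_equal(res$summary$mean[5], mean(emb_means))
  expect_equal(res$summary$sd[5], sd(emb_means))
})
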