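#' Interpolate short segmentation gaps in a trace
#'
#' Interior runs of missing area values shorter than three time points (i.e.
#' of length `<= max_gap`) are filled by linear interpolation between the
#' flanking measurements; longer runs are left missing. Leading and trailing
#' missing samples have no anchor on one side and are trimmed.
#'
#' @param trace a [cell_trace()].
#' @param max_gap longest missing run that is still interpolated (default 2).
#' @return A [cell_trace()] with gaps filled and edges trimmed. The optional
#'   intensity/anisotropy channels are carried through (subset, not
#'   interpolated).
#' @export
interpolate_gaps <- function(trace, max_gap = 2) {
  stopifnot(inherits(trace, "cell_trace"))
  pres <- present_idx(trace)
  if (length(pres) == 0) ap_stop("trace has no measured area values", "empty_trace")
  keep <- seq(min(pres), max(pres))
  a <- trace$area_um2[keep]
  t <- trace$times_s[keep]
  if (anyNA(a)) {
    r <- rle(is.na(a))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    filled <- stats::approx(t[!is.na(a)], a[!is.na(a)], xout = t)$y
    for (i in which(r$values & r$lengths <= max_gap))
      a[starts[i]:ends[i]] <- filled[starts[i]:ends[i]]
  }
  cell_trace(times_s = t, area_um2 = a,
             intensity = trace$intensity[keep], anisotropy = trace$anisotropy[keep],
             embryo_id = trace$embryo_id, cell_id = trace$cell_id)
}

#' Centered moving-average smoothing
#'
#' Smooths a numeric sequence with a centered moving mean. Near the
#' boundaries the window is truncated symmetrically (no padding), so the
#' output has the same length as the input. Even window sizes are reduced to
#' the next smaller odd size so the window stays centered.
#'
#' @param x numeric sequence (may contain `NA`, which propagate into any
#'   window touching them).
#' @param window_points nominal window size in samples; `1` is the identity.
#' @return numeric vector of the same length as `x`.
#' @export
smooth_moving_mean <- function(x, window_points) {
  n <- length(x)
  if (n == 0) ap_stop("empty series", "empty_input")
  if (window_points < 1 || window_points > n)
    ap_stop("window_points must be in [1, length(x)]", "invalid_parameters")
  h <- (as.integer(window_points) - 1L) %/% 2L
  if (h == 0L) return(as.numeric(x))
  vapply(seq_len(n), function(i) {
    r <- min(h, i - 1L, n - i)
    mean(x[(i - r):(i + r)])
  }, numeric(1))
}

#' Constriction rate of an apical-area trace
#'
#' The rate of apical area loss, computed as the negated finite-difference
#' quotient of area over time, converted to um^2/min and assigned to the
#' interval midpoints, then smoothed with a centered moving mean. Positive
#' values mean the cell is constricting; the expansion rate is the negated
#' constriction rate.
#'
#' @param trace a [cell_trace()]; needs at least two samples, sampled
#'   approximately uniformly (max/min interval ratio below 2).
#' @param smooth_window moving-mean window in samples (default 10,
#'   corresponding to ~38 s at 3.8 s sampling); use 1 for the unsmoothed rate
#'   that pulse-peak detection operates on.
#' @return A data frame of class `rate_series` with columns `times_s` and
#'   `rate_um2_per_min`, and attributes `smoothed`, `window_points`,
#'   `embryo_id`, `cell_id`.
#' @export
constriction_rate <- function(trace, smooth_window = 10) {
  stopifnot(inherits(trace, "cell_trace"))
  n <- length(trace$times_s)
  if (sum(!is.na(trace$area_um2)) < 2) ap_stop("need at least two measured samples", "too_short")
  dtv <- diff(trace$times_s)
  if (max(dtv) / min(dtv) >= 2)
    ap_stop("sampling too nonuniform for a rate series (max/min interval >= 2)", "nonuniform_sampling")
  rate <- -diff(trace$area_um2) / dtv * 60
  mid <- trace$times_s[-n] + dtv / 2
  sw <- max(1L, min(as.integer(smooth_window), length(rate)))
  out <- data.frame(times_s = mid,
                    rate_um2_per_min = if (sw > 1) smooth_moving_mean(rate, sw) else rate)
  structure(out, class = c("rate_series", "data.frame"),
            smoothed = sw > 1, window_points = sw,
            embryo_id = trace$embryo_id, cell_id = trace$cell_id)
}

#' Remove the slow trend from an area trace by cubic polynomial fit
#'
#' Fits a 3rd-degree polynomial to area over time by least squares and
#' returns the residual ("normalized") signal on which pulsation extrema are
#' detected. Residual plus evaluated trend reconstructs the input to
#' numerical tolerance.
#'
#' @param trace a [cell_trace()] with at least 5 measured samples.
#' @return A list of class `detrended_trace` with `times_s`, `area_um2`,
#'   `residual_um2`, `trend_um2` (all trace-length, `NA` at missing frames)
#'   and `trend_coeffs` (ascending, length 4).
#' @export
detrend_area <- function(trace) {
  stopifnot(inherits(trace, "cell_trace"))
  pres <- present_idx(trace)
  if (length(pres) < 5) ap_stop("need at least 5 measured samples for a cubic fit", "too_short")
  t <- trace$times_s
  fit <- stats::lm(a ~ t1 + t2 + t3,
                   data = data.frame(a = trace$area_um2[pres], t1 = t[pres],
                                     t2 = t[pres]^2, t3 = t[pres]^3))
  co <- unname(stats::coef(fit))
  trend <- polyval_asc(co, t)
  structure(list(times_s = t, area_um2 = trace$area_um2,
                 residual_um2 = trace$area_um2 - trend,
                 trend_um2 = trend, trend_coeffs = co,
                 embryo_id = trace$embryo_id, cell_id = trace$cell_id),
            class = "detrended_trace")
}

# plateau-aware strict local maxima on a numeric vector: a run of equal
# values strictly above both flanking runs reports its first sample;
# endpoints (and runs touching them) are never extrema
local_maxima_idx <- function(x) {
  if (anyNA(x)) ap_stop("series must not contain NA for extrema detection", "invalid_parameters")
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(as.numeric(x))
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(k - 1)
  hit <- r$values[i] > r$values[i - 1] & r$values[i] > r$values[i + 1]
  starts[i][hit]
}

#' Detect strict local extrema (pulsation peaks) in a series
#'
#' Finds strict local maxima or minima: samples greater (smaller) than both
#' neighbours. A flat-topped plateau strictly above (below) both flanks is
#' reported at its first sample; series endpoints are never extrema. Minima
#' are found by negating the series.
#'
#' @param series numeric sequence without `NA`.
#' @param kind `"maxima"` or `"minima"`.
#' @param times_s optional event timestamps, same length as `series`
#'   (defaults to the sample index).
#' @return A data frame of class `pulse_events` with columns `index`,
#'   `time_s`, `value`, and attribute `kind`. Empty (zero rows) when the
#'   series is shorter than 3 or has no extrema.
#' @export
find_local_extrema <- function(series, kind = c("maxima", "minima"), times_s = NULL) {
  kind <- match.arg(kind)
  x <- if (kind == "minima") -as.numeric(series) else as.numeric(series)
  idx <- local_maxima_idx(x)
  if (is.null(times_s)) times_s <- seq_along(series)
  structure(data.frame(index = idx, time_s = times_s[idx],
                       value = as.numeric(series)[idx]),
            class = c("pulse_events", "data.frame"), kind = kind)
}

#' Per-cell ratchet statistic: mean area difference between consecutive peaks
#'
#' Quantifies ratcheting from one trace: the area signal is detrended by a
#' cubic fit ([detrend_area()]), local maxima and minima of the residual are
#' located, and the mean difference in area between consecutive maxima (and,
#' separately, consecutive minima) is computed and averaged into a single
#' per-cell value, expressed as percent of the initial area per pulse
#' interval. Negative values indicate incremental shrinkage upon pulsation
#' (ratcheting); values around zero indicate relaxation back to the previous
#' state.
#'
#' By default the differences are evaluated on the raw area at the detected
#' extrema, so the trend-borne incremental decrease is part of the statistic;
#' `on_raw = FALSE` evaluates them on the detrended residual instead.
#'
#' @param trace a [cell_trace()].
#' @param on_raw logical; evaluate consecutive-peak differences on the raw
#'   area (default) or on the detrended residual.
#' @param smooth_window optional moving-mean window applied to the area
#'   before detrending (default 1 = none); useful for noisy traces where
#'   plain neighbour-scan extrema would be dominated by noise.
#' @return A list of class `ratchet_result`: `cell_id`, `mean_interpeak_diff`
#'   (percent of initial area), `n_maxima`, `n_minima`, and the per-kind
#'   means.
#' @export
ratchet_amplitude <- function(trace, on_raw = TRUE, smooth_window = 1) {
  stopifnot(inherits(trace, "cell_trace"))
  pres <- present_idx(trace)
  if (length(pres) < 5) ap_stop("too few measured samples", "too_short")
  t <- trace$times_s[pres]
  a <- trace$area_um2[pres]
  if (smooth_window > 1) a <- smooth_moving_mean(a, smooth_window)
  dtr <- detrend_area(cell_trace(t, a, embryo_id = trace$embryo_id, cell_id = trace$cell_id))
  initial <- a[1]
  signal <- if (on_raw) a else dtr$residual_um2
  # residuals below 1 nm^2 are numerically flat, not pulsation; rounding
  # keeps float jitter on degenerate (e.g. perfectly linear) traces from
  # masquerading as extrema
  resid <- round(dtr$residual_um2, 9)
  kind_mean <- function(kind) {
    ev <- find_local_extrema(resid, kind, times_s = t)
    if (nrow(ev) < 2) return(list(m = NA_real_, n = nrow(ev)))
    list(m = mean(diff(signal[ev$index])) / initial * 100, n = nrow(ev))
  }
  mx <- kind_mean("maxima")
  mn <- kind_mean("minima")
  if (is.na(mx$m) && is.na(mn$m))
    ap_stop("fewer than 2 maxima and fewer than 2 minima: not enough pulses", "not_enough_pulses")
  structure(list(cell_id = trace$cell_id,
                 mean_interpeak_diff = mean(c(mx$m, mn$m), na.rm = TRUE),
                 n_maxima = mx$n, n_minima = mn$n,
                 maxima_mean = mx$m, minima_mean = mn$m),
            class = "ratchet_result")
}

#' Positive pulsation peaks of a constriction-rate series
#'
#' Locates pulsation peaks on the unsmoothed constriction rate: local maxima
#' of the rate (constriction polarity) or of the negated rate (expansion
#' polarity). Peaks with non-positive values are discarded.
#'
#' @param rate a `rate_series` from [constriction_rate()]; should be computed
#'   with `smooth_window = 1` (a warning is issued otherwise).
#' @param polarity `"constriction"` or `"expansion"`.
#' @return A `pulse_events` data frame; `value` is the peak rate in
#'   um^2/min in the polarity's own sign (always positive).
#' @export
find_rate_peaks <- function(rate, polarity = c("constriction", "expansion")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(rate, "rate_series"))
  if (isTRUE(attr(rate, "smoothed")))
    warning("pulse peaks are defined on the unsmoothed rate; got a smoothed series")
  x <- rate$rate_um2_per_min
  if (polarity == "expansion") x <- -x
  ev <- find_local_extrema(x, "maxima", times_s = rate$times_s)
  ev <- ev[ev$value > 0, , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("pulse_events", "data.frame"),
            kind = paste0("rate_", polarity, "_peak"))
}

#' Mean pulsation-peak rate of one cell
#'
#' Computes the unsmoothed constriction rate, detects positive pulsation
#' peaks of the requested polarity, and returns their arithmetic mean for the
#' cell, in um^2/min.
#'
#' @param trace a [cell_trace()].
#' @param polarity `"constriction"` or `"expansion"`.
#' @return scalar mean peak rate (um^2/min).
#' @export
mean_peak_rate <- function(trace, polarity = c("constriction", "expansion")) {
  polarity <- match.arg(polarity)
  peaks <- find_rate_peaks(constriction_rate(trace, smooth_window = 1), polarity)
  if (nrow(peaks) == 0)
    ap_stop(sprintf("cell %s has no positive %s peaks", trace$cell_id, polarity), "no_peaks")
  mean(peaks$value)
}

#' Categorize a cell's cumulative constriction after 7 minutes
#'
#' The 3-point-smoothed apical area at the sample nearest `eval_time_s` after
#' trace onset, divided by the initial (smoothed) area, classifies the cell:
#' ratio below 0.5 is `constricted`, between 0.5 and 1 (inclusive) is
#' `impaired`, strictly above 1 is `expanded`.
#'
#' @param trace a [cell_trace()] tracked at least to `eval_time_s`.
#' @param eval_time_s evaluation time after trace onset, seconds (default
#'   420 = 7 min).
#' @param smooth_window moving-mean window applied to the area first.
#' @return A list of class `cell_category`: `label` (factor over
#'   constricted/impaired/expanded), `area_ratio_at_eval`, `cell_id`.
#' @export
categorize_cell <- function(trace, eval_time_s = 420, smooth_window = 3) {
  stopifnot(inherits(trace, "cell_trace"))
  pres <- present_idx(trace)
  t <- trace$times_s[pres]
  elapsed <- t - t[1]
  dt_med <- stats::median(diff(t))
  if (max(elapsed) < eval_time_s - dt_med / 2)
    ap_stop(sprintf("cell %s not tracked up to %g s", trace$cell_id, eval_time_s),
            "untracked_at_eval")
  sm <- smooth_moving_mean(trace$area_um2[pres], smooth_window)
  ratio <- sm[which.min(abs(elapsed - eval_time_s))] / sm[1]
  label <- if (ratio < 0.5) "constricted" else if (ratio <= 1) "impaired" else "expanded"
  structure(list(label = factor(label, levels = c("constricted", "impaired", "expanded")),
                 area_ratio_at_eval = ratio, cell_id = trace$cell_id),
            class = "cell_category")
}

#' Exclude cells tracked much shorter than the cohort median
#'
#' Computes each cell's tracked duration (last minus first measured frame)
#' and removes cells whose duration falls below the cohort median minus one
#' standard deviation of the durations.
#'
#' @param cohort a `trace_cohort` (list of [cell_trace()]).
#' @return list with `cohort` (kept traces) and `report` (data frame with
#'   per-cell duration and exclusion flag).
#' @export
exclude_short_tracks <- function(cohort) {
  if (length(cohort) == 0)
    return(list(cohort = as_trace_cohort(list()),
                report = data.frame(cell_id = character(0), embryo_id = character(0),
                                    duration_s = numeric(0), excluded = logical(0))))
  dur <- vapply(cohort, function(tr) {
    t <- tr$times_s[present_idx(tr)]
    max(t) - min(t)
  }, numeric(1))
  cutoff <- if (length(dur) >= 2) stats::median(dur) - stats::sd(dur) else -Inf
  excl <- dur < cutoff
  report <- data.frame(
    cell_id = vapply(cohort, `[[`, "", "cell_id"),
    embryo_id = vapply(cohort, `[[`, "", "embryo_id"),
    duration_s = dur, excluded = excl, stringsAsFactors = FALSE)
  list(cohort = as_trace_cohort(unclass(cohort)[!excl]), report = report)
}

#' Peak-triggered average of area, rate, and reporter intensity
#'
#' Aligns windows of +/- `half_window_s` seconds around isolated pulsation
#' peaks (lag 0 at the peak) across all cells and returns the per-lag mean
#' and SD of the apical area, the unsmoothed constriction rate, and (when
#' present) the reporter intensity. A peak is isolated when no other peak of
#' the same polarity lies within the half window; windows truncated by the
#' trace ends are dropped, not padded. Signals are linearly interpolated onto
#' the common lag grid.
#'
#' @param cohort a `trace_cohort` or a single [cell_trace()].
#' @param polarity `"constriction"` or `"expansion"` peaks to trigger on.
#' @param half_window_s half window in seconds (default 25, i.e. a 50-s
#'   window).
#' @return A data frame of class `triggered_average` with `lag_s` and
#'   mean/sd columns per signal; attribute `n_peaks`.
#' @export
peak_triggered_average <- function(cohort, polarity = c("constriction", "expansion"),
                                   half_window_s = 25) {
  polarity <- match.arg(polarity)
  if (inherits(cohort, "cell_trace")) cohort <- as_trace_cohort(list(cohort))
  dts <- unlist(lapply(cohort, function(tr) diff(tr$times_s)))
  dt <- stats::median(dts)
  m <- ceiling(half_window_s / dt)
  lags <- seq(-half_window_s, half_window_s, length.out = 2 * m + 1)
  rows_area <- list(); rows_rate <- list(); rows_int <- list()
  n_peaks <- 0L
  for (tr in cohort) {
    rate <- constriction_rate(tr, smooth_window = 1)
    peaks <- tryCatch(find_rate_peaks(rate, polarity), error = function(e) NULL)
    if (is.null(peaks) || nrow(peaks) == 0) next
    for (i in seq_len(nrow(peaks))) {
      pt <- peaks$time_s[i]
      others <- peaks$time_s[-i]
      if (length(others) > 0 && min(abs(others - pt)) <= half_window_s) next
      if (pt - half_window_s < rate$times_s[1] || pt + half_window_s > rate$times_s[nrow(rate)]) next
      if (pt - half_window_s < tr$times_s[1] || pt + half_window_s > tr$times_s[length(tr$times_s)]) next
      grid <- pt + lags
      n_peaks <- n_peaks + 1L
      rows_area[[n_peaks]] <- stats::approx(tr$times_s, tr$area_um2, xout = grid)$y
      rows_rate[[n_peaks]] <- stats::approx(rate$times_s, rate$rate_um2_per_min, xout = grid)$y
      rows_int[[n_peaks]] <- if (!is.null(tr$intensity))
        stats::approx(tr$times_s, tr$intensity, xout = grid)$y else rep(NA_real_, length(grid))
    }
  }
  if (n_peaks == 0) ap_stop("no isolated peaks in the requested window", "no_events")
  stat2 <- function(rows) {
    m <- do.call(rbind, rows)
    sd <- apply(m, 2, stats::sd)
    sd[is.na(sd)] <- 0   # a single peak has zero spread by convention
    list(mean = colMeans(m), sd = sd)
  }
  a <- stat2(rows_area); r <- stat2(rows_rate); i <- stat2(rows_int)
  structure(data.frame(lag_s = lags,
                       area_mean = a$mean, area_sd = a$sd,
                       rate_mean = r$mean, rate_sd = r$sd,
                       intensity_mean = i$mean, intensity_sd = i$sd),
            class = c("triggered_average", "data.frame"),
            n_peaks = n_peaks, polarity = polarity)
}

#' Two-stage per-embryo averaging of a cohort signal
#'
#' Stage 1 averages cells within each embryo at each time point; stage 2
#' averages the embryo means and reports the across-embryo SD, so every
#' embryo carries equal weight regardless of its cell count.
#'
#' @param cohort a `trace_cohort`.
#' @param signal which per-cell channel to average: `"area_um2"` or
#'   `"intensity"`.
#' @return list with `per_embryo` (data frame time_s x embryo means) and
#'   `summary` (data frame with `time_s`, `mean`, `sd`, `n_embryos`).
#' @export
per_embryo_average <- function(cohort, signal = c("area_um2", "intensity")) {
  signal <- match.arg(signal)
  if (length(cohort) == 0) ap_stop("empty cohort", "empty_input")
  recs <- do.call(rbind, lapply(cohort, function(tr) {
    v <- tr[[signal]]
    if (is.null(v)) return(NULL)
    data.frame(embryo = tr$embryo_id, time = round(tr$times_s, 6), value = v)
  }))
  recs <- recs[!is.na(recs$value), ]
  stage1 <- stats::aggregate(value ~ embryo + time, data = recs, FUN = mean)
  times <- sort(unique(stage1$time))
  embryos <- sort(unique(stage1$embryo))
  wide <- matrix(NA_real_, length(times), length(embryos),
                 dimnames = list(NULL, embryos))
  wide[cbind(match(stage1$time, times), match(stage1$embryo, embryos))] <- stage1$value
  mean2 <- rowMeans(wide, na.rm = TRUE)
  n_emb <- rowSums(!is.na(wide))
  sd2 <- apply(wide, 1, function(v) if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  list(per_embryo = data.frame(time_s = times, wide, check.names = FALSE),
       summary = data.frame(time_s = times, mean = mean2, sd = sd2, n_embryos = n_emb))
}
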