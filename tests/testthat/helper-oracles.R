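# shared fixtures and independent oracles used across test files

mk_trace <- function(area, dt = 3.8, ...) {
  cell_trace(times_s = (seq_along(area) - 1) * dt, area_um2 = area, ...)
}

# exhaustive neighbour-scan local-maxima oracle with plateau handling:
# walks every sample, expands plateaus explicitly, checks both flanks
oracle_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1L
    if (i > 1 && j < n && x[i - 1] < x[i] && x[j + 1] < x[i]) out <- c(out, i)
    i <- j + 1L
  }
  out
}

# brute-force centered moving mean with symmetric truncation (odd windows)
oracle_moving_mean <- function(x, w) {
  h <- (w - 1) %/% 2
  n <- length(x)
  sapply(seq_len(n), function(i) {
    r <- min(h, i - 1, n - i)
    mean(x[(i - r):(i + r)])
  })
}

# random pulsatile-ish integer sequence: small value range forces ties and
# plateaus, exercising the extrema plateau rule
random_plateau_seq <- function(n, k = 5) sample.int(k, n, replace = TRUE)
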