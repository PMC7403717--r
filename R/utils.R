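# internal helpers: conditions, seeded RNG scopes, small numerics

ap_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("ap_", class), "ap_error", "error", "condition")))
}

#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit hash of ids, used to derive independent per-cell RNG
# streams from one global seed; products stay < 2^53 so doubles are exact
stable_hash <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\r")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

# normal draws truncated by rejection at mean +/- k sd and floored; keeps
# generator parameter draws inside the range the closed-form calibration covers
rnorm_clipped <- function(n, mean, sd, k = 2.5, lower = -Inf) {
  x <- stats::rnorm(n, mean, sd)
  x <- pmin(pmax(x, mean - k * sd), mean + k * sd)
  pmax(x, lower)
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# separable Gaussian smoothing of a matrix with replicate padding; a constant
# matrix is preserved exactly (kernel is normalized), which the flat-phantom
# exactness invariant of surface_project() relies on
gauss_smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(v) {
    vp <- c(rep(v[1L], r), v, rep(v[length(v)], r))
    out <- as.numeric(stats::filter(vp, k, sides = 2))
    out[(r + 1L):(r + length(v))]
  }
  nr <- nrow(m); nc <- ncol(m)
  m1 <- if (nr > 1) apply(m, 2, conv1) else m
  m1 <- matrix(m1, nr, nc)
  m2 <- if (nc > 1) t(apply(m1, 1, conv1)) else m1
  matrix(m2, nr, nc)
}

# evaluate polynomial with ascending coefficients c0 + c1 t + c2 t^2 + ...
polyval_asc <- function(coeffs, t) {
  out <- numeric(length(t))
  for (i in seq_along(coeffs)) out <- out + coeffs[i] * t^(i - 1)
  out
}

# write-then-rename so interrupted runs never leave half-written files
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) ap_stop(sprintf("could not move temp file onto '%s'", path), "write_failed")
  invisible(path)
}
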