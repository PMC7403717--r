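# grid tiling used by the surface projection: starts every grid_size px,
# remainder absorbed into the last tile
tile_bounds <- function(n, grid_size) {
  starts <- seq.int(1L, n, by = grid_size)
  ends <- c(starts[-1] - 1L, n)
  keep <- starts <= n
  cbind(start = starts[keep], end = ends[keep])
}

# fractional slice weights for a band [h - T/2, h + T/2]; slice s covers
# [s - 0.5, s + 0.5], partial overlaps get proportional weight
band_weights <- function(h, thickness, nz) {
  lo <- h - thickness / 2
  hi <- h + thickness / 2
  s <- seq_len(nz)
  w <- pmax(0, pmin(s + 0.5, hi) - pmax(s - 0.5, lo))
  if (sum(w) == 0) w[max(1L, min(nz, round(h)))] <- 1
  w / sum(w)
}

# one grid-projection pass over a [y, x, z] volume
project_pass <- function(vox, grid_size, gauss_sigma, thickness) {
  d <- dim(vox)
  ty <- tile_bounds(d[1], grid_size)
  tx <- tile_bounds(d[2], grid_size)
  h_raw <- matrix(NA_real_, nrow(ty), nrow(tx))
  for (i in seq_len(nrow(ty))) {
    for (j in seq_len(nrow(tx))) {
      sub <- vox[ty[i, 1]:ty[i, 2], tx[j, 1]:tx[j, 2], , drop = FALSE]
      zprof <- apply(sub, 3, sum)
      h_raw[i, j] <- which.max(zprof)      # ties resolve to the apical-most slice
    }
  }
  h_f <- gauss_smooth_matrix(h_raw, gauss_sigma)
  proj <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(nrow(ty))) {
    for (j in seq_len(nrow(tx))) {
      w <- band_weights(h_f[i, j], thickness, d[3])
      sl <- which(w > 0)
      acc <- matrix(0, ty[i, 2] - ty[i, 1] + 1L, tx[j, 2] - tx[j, 1] + 1L)
      for (s in sl) acc <- acc + w[s] * vox[ty[i, 1]:ty[i, 2], tx[j, 1]:tx[j, 2], s]
      proj[ty[i, 1]:ty[i, 2], tx[j, 1]:tx[j, 2]] <- acc
    }
  }
  list(projection = proj, height_raw = h_raw, height_filtered = h_f)
}

#' Grid-based surface projection of a confocal stack
#'
#' Extracts the curved bright surface of an epithelium from a 3D stack and
#' flattens it into a 2D image. The stack is split into an x/y grid; within
#' each grid unit the per-slice summed z-intensity profile locates the
#' surface peak (argmax, ties to the apical-most slice). The resulting height
#' map is smoothed with a Gaussian (sigma in grid units), and each unit is
#' mean-projected over the slices overlapping a band of
#' `thickness_slices` centered at the (fractional) filtered height, with
#' proportional weights for partially covered slices. To suppress grid-edge
#' artefacts the whole procedure is repeated on a copy of the stack padded by
#' half a grid unit in x and y (padding filled per slice with the mean
#' intensity of that slice's outer margin, margin width half a grid unit),
#' which shifts the grid by half a unit; the final projection is the
#' pixelwise mean of the two passes.
#'
#' @param stack an [image_stack()] with at least 2 slices.
#' @param grid_size_px grid unit edge length in pixels (default 16).
#' @param gauss_sigma_units SD of the Gaussian height-map filter, in grid
#'   units (default 1).
#' @param thickness_slices band thickness projected around the surface, in
#'   slices (default 3).
#' @return list with `projection` (matrix `[y, x]`) and `height_map`, a
#'   matrix of filtered surface heights (fractional slice index, apical = 1)
#'   per grid unit with attributes `grid_size_px` and `height_raw`.
#' @export
surface_project <- function(stack, grid_size_px = 16, gauss_sigma_units = 1,
                            thickness_slices = 3) {
  if (grid_size_px < 2) ap_stop("grid_size_px must be >= 2", "invalid_parameters")
  d <- dim(stack)
  if (d[3] < 2) ap_stop("need at least two slices", "invalid_parameters")
  if (d[1] < grid_size_px || d[2] < grid_size_px)
    ap_stop("stack smaller than one grid unit", "too_small")
  vox <- unclass(stack)
  attributes(vox) <- list(dim = d)

  p1 <- project_pass(vox, grid_size_px, gauss_sigma_units, thickness_slices)

  pad <- grid_size_px %/% 2L
  vox_p <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  for (s in seq_len(d[3])) {
    sl <- vox[, , s]
    # outer margin of width `pad`; if the slice is too small to have an
    # interior the margin is the whole slice
    has_inner <- d[1] > 2L * pad && d[2] > 2L * pad
    inner_sum <- if (has_inner) sum(sl[(pad + 1):(d[1] - pad), (pad + 1):(d[2] - pad)]) else 0
    inner_n <- if (has_inner) (d[1] - 2L * pad) * (d[2] - 2L * pad) else 0L
    margin_mean <- (sum(sl) - inner_sum) / (length(sl) - inner_n)
    page <- matrix(margin_mean, d[1] + 2L * pad, d[2] + 2L * pad)
    page[pad + seq_len(d[1]), pad + seq_len(d[2])] <- sl
    vox_p[, , s] <- page
  }
  p2 <- project_pass(vox_p, grid_size_px, gauss_sigma_units, thickness_slices)
  proj2 <- p2$projection[pad + seq_len(d[1]), pad + seq_len(d[2])]

  height_map <- p1$height_filtered
  attr(height_map, "grid_size_px") <- grid_size_px
  attr(height_map, "height_raw") <- p1$height_raw
  class(height_map) <- c("height_map", class(height_map))
  list(projection = (p1$projection + proj2) / 2, height_map = height_map)
}

#' Aggregate a per-pixel height truth map onto the projection grid
#'
#' Averages a per-pixel surface-height map over the same grid tiling that
#' [surface_project()] uses, for comparing a phantom's ground truth with the
#' recovered height map.
#'
#' @param heights_px numeric matrix `[y, x]` of per-pixel heights (slice
#'   index units).
#' @param grid_size_px grid unit edge length in pixels.
#' @return matrix of per-grid-unit mean heights.
#' @export
bin_height_map <- function(heights_px, grid_size_px) {
  ty <- tile_bounds(nrow(heights_px), grid_size_px)
  tx <- tile_bounds(ncol(heights_px), grid_size_px)
  out <- matrix(NA_real_, nrow(ty), nrow(tx))
  for (i in seq_len(nrow(ty)))
    for (j in seq_len(nrow(tx)))
      out[i, j] <- mean(heights_px[ty[i, 1]:ty[i, 2], tx[j, 1]:tx[j, 2]])
  out
}
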