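#' Parameters for a 3D surface phantom
#'
#' Describes a synthetic confocal stack containing a bright curved surface of
#' known height, used as ground truth for [surface_project()]. The surface
#' has a quartic axial intensity profile
#' `w(dz) = max(0, 1 - (dz / ((thickness + 1)/2))^4)`, which is strictly
#' peaked (so the per-column brightest slice is the nearest slice to the true
#' height) yet nearly flat across the band (so a band projection recovers
#' close to the full surface intensity).
#'
#' @param shape_zyx integer vector `c(n_z, n_y, n_x)` of voxel counts.
#' @param pixel_size_um,z_step_um physical calibration.
#' @param height_function one of `"flat"`, `"tilted_plane"`, `"sinusoid"`,
#'   `"paraboloid"`.
#' @param height_args named list of profile parameters (slice-index units,
#'   apical slice = 1): `z0` (base height); `slope_x`, `slope_y` (slices per
#'   pixel, tilted plane); `amplitude`, `wavelength_px` (sinusoid along x);
#'   `depth` (paraboloid sag at the corners).
#' @param surface_intensity,background_level intensities in a.u.;
#'   `surface_intensity` must exceed `background_level`.
#' @param surface_thickness_slices nominal thickness of the bright band.
#' @param noise_sd SD of additive Gaussian noise.
#' @param blur_sigma_px lateral Gaussian blur applied per slice.
#' @param seed integer seed.
#' @return validated list of class `surface_phantom_params`.
#' @export
surface_phantom_params <- function(shape_zyx = c(12, 64, 64), pixel_size_um = 0.2,
                                   z_step_um = 0.5, height_function = "flat",
                                   height_args = list(z0 = 6),
                                   surface_intensity = 100,
                                   surface_thickness_slices = 3,
                                   background_level = 2, noise_sd = 0,
                                   blur_sigma_px = 0, seed = 1) {
  height_function <- match.arg(height_function,
                               c("flat", "tilted_plane", "sinusoid", "paraboloid"))
  if (surface_intensity <= background_level)
    ap_stop("surface_intensity must exceed background_level", "invalid_parameters")
  if (any(shape_zyx < c(2, 1, 1))) ap_stop("stack must have at least 2 slices", "invalid_parameters")
  structure(list(shape_zyx = as.integer(shape_zyx), pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, height_function = height_function,
                 height_args = height_args, surface_intensity = surface_intensity,
                 surface_thickness_slices = surface_thickness_slices,
                 background_level = background_level, noise_sd = noise_sd,
                 blur_sigma_px = blur_sigma_px, seed = as.integer(seed)),
            class = "surface_phantom_params")
}

phantom_heights <- function(params) {
  nz <- params$shape_zyx[1]; ny <- params$shape_zyx[2]; nx <- params$shape_zyx[3]
  a <- params$height_args
  x <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
  y <- matrix(rep(seq_len(ny) - 1, times = nx), ny, nx)
  z0 <- if (is.null(a$z0)) (nz + 1) / 2 else a$z0
  h <- switch(params$height_function,
    flat = matrix(z0, ny, nx),
    tilted_plane = z0 + (if (is.null(a$slope_x)) 0 else a$slope_x) * x +
      (if (is.null(a$slope_y)) 0 else a$slope_y) * y,
    sinusoid = z0 + (if (is.null(a$amplitude)) 1.5 else a$amplitude) *
      sin(2 * pi * x / (if (is.null(a$wavelength_px)) 64 else a$wavelength_px)),
    paraboloid = {
      depth <- if (is.null(a$depth)) 2 else a$depth
      r2 <- ((x - (nx - 1) / 2)^2 + (y - (ny - 1) / 2)^2)
      z0 + depth * r2 / max(r2)
    })
  if (any(h < 1) || any(h > nz))
    ap_stop("height function leaves the z-range of the stack", "invalid_parameters")
  h
}

#' Generate a surface phantom stack with known height map
#'
#' Builds an [image_stack()] containing a bright band centered on a known
#' surface, plus optional lateral blur and Gaussian noise.
#'
#' @param params a [surface_phantom_params()] object.
#' @return list with `stack` (an [image_stack()]) and `heights_px`, the true
#'   per-pixel surface height in slice-index units (compare against a
#'   recovered height map via [bin_height_map()]).
#' @export
gen_surface_phantom <- function(params) {
  stopifnot(inherits(params, "surface_phantom_params"))
  nz <- params$shape_zyx[1]; ny <- params$shape_zyx[2]; nx <- params$shape_zyx[3]
  h <- phantom_heights(params)
  half <- (params$surface_thickness_slices + 1) / 2
  vox <- array(params$background_level, dim = c(ny, nx, nz))
  for (s in seq_len(nz)) {
    w <- pmax(1 - (abs(s - h) / half)^4, 0)   # first arg keeps the matrix dim
    sl <- params$background_level + params$surface_intensity * w
    if (params$blur_sigma_px > 0) sl <- gauss_smooth_matrix(sl, params$blur_sigma_px)
    vox[, , s] <- sl
  }
  if (params$noise_sd > 0)
    vox <- with_seed(params$seed,
                     vox + array(stats::rnorm(length(vox), 0, params$noise_sd), dim = dim(vox)))
  list(stack = image_stack(vox, params$pixel_size_um, params$z_step_um),
       heights_px = h)
}

#' Parameters for a labelled synthetic movie
#'
#' Describes a 2D time-lapse of labelled cells with prescribed pixel-area
#' trajectories and reporter intensities, the fixture for per-cell intensity
#' quantification. Cells are laid out on non-overlapping rectangular slots;
#' each cell is drawn as a rectangle of fixed width whose height tracks the
#' requested area, so realized areas match the request to within one pixel
#' row.
#'
#' @param n_cells number of cells.
#' @param frame_shape `c(n_y, n_x)` pixels.
#' @param n_frames number of frames.
#' @param areas_px matrix `[n_frames, n_cells]` of target pixel areas, or a
#'   single number recycled.
#' @param intensities matrix `[n_frames, n_cells]` of per-cell reporter
#'   intensities (a.u.), or a vector of per-cell constants.
#' @param cell_width_px rectangle width in pixels.
#' @param noise_sd additive Gaussian noise on the intensity movie.
#' @param seed integer seed.
#' @return validated list of class `labeled_movie_params`.
#' @export
labeled_movie_params <- function(n_cells = 4, frame_shape = c(64, 64), n_frames = 10,
                                 areas_px = 80, intensities = 100,
                                 cell_width_px = 8, noise_sd = 0, seed = 1) {
  if (n_cells < 1 || n_frames < 1) ap_stop("need at least one cell and frame", "invalid_parameters")
  expand <- function(m) {
    if (is.matrix(m)) {
      if (!all(dim(m) == c(n_frames, n_cells)))
        ap_stop("matrix parameters must be [n_frames, n_cells]", "invalid_parameters")
      m
    } else matrix(m, n_frames, n_cells, byrow = length(m) == n_cells)
  }
  structure(list(n_cells = as.integer(n_cells), frame_shape = as.integer(frame_shape),
                 n_frames = as.integer(n_frames), areas_px = expand(areas_px),
                 intensities = expand(intensities),
                 cell_width_px = as.integer(cell_width_px),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "labeled_movie_params")
}

#' Generate a labelled movie with matching intensity movie
#'
#' @param params a [labeled_movie_params()] object.
#' @return list with `labels` (integer array `[y, x, frame]`, background 0),
#'   `intensity` (numeric array of the same shape), and `truth` (realized
#'   per-frame pixel areas and prescribed intensities).
#' @export
gen_labeled_movie <- function(params) {
  stopifnot(inherits(params, "labeled_movie_params"))
  ny <- params$frame_shape[1]; nx <- params$frame_shape[2]
  w <- params$cell_width_px
  slot_h <- max(ceiling(max(params$areas_px) / w) + 2L, 4L)
  slot_w <- w + 2L
  n_sx <- nx %/% slot_w
  n_sy <- ny %/% slot_h
  if (n_sx * n_sy < params$n_cells)
    ap_stop("cells do not fit the frame without overlap", "layout_infeasible")
  labels <- array(0L, dim = c(ny, nx, params$n_frames))
  intens <- array(0, dim = c(ny, nx, params$n_frames))
  realized <- matrix(0L, params$n_frames, params$n_cells)
  for (c in seq_len(params$n_cells)) {
    sy <- ((c - 1L) %/% n_sx) * slot_h + 1L
    sx <- ((c - 1L) %% n_sx) * slot_w + 1L
    for (f in seq_len(params$n_frames)) {
      h <- max(1L, min(slot_h - 2L, as.integer(round(params$areas_px[f, c] / w))))
      ys <- sy:(sy + h - 1L); xs <- sx:(sx + w - 1L)
      labels[ys, xs, f] <- c
      intens[ys, xs, f] <- params$intensities[f, c]
      realized[f, c] <- h * w
    }
  }
  if (params$noise_sd > 0)
    intens <- with_seed(params$seed,
                        intens + array(stats::rnorm(length(intens), 0, params$noise_sd),
                                       dim = dim(intens)))
  list(labels = labels, intensity = intens,
       truth = list(areas_px = realized, intensities = params$intensities))
}
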