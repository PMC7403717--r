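#' Calibrated 3D fluorescence image stack
#'
#' A confocal stack stored as a `[y, x, z]` array with physical calibration.
#' Slice `z = 1` is the most apical focal plane; the slice index increases
#' with depth, so the "lowest" focal plane is the last slice.
#'
#' @param voxels numeric array `[y, x, z]` of intensities (a.u.).
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um axial spacing between slices in micrometres.
#' @param time_s optional acquisition time in seconds.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, pixel_size_um, z_step_um, time_s = NULL) {
  if (length(dim(voxels)) != 3) ap_stop("voxels must be a [y, x, z] array", "invalid_parameters")
  if (pixel_size_um <= 0 || z_step_um <= 0) ap_stop("calibrations must be positive", "invalid_parameters")
  structure(voxels, class = "image_stack", pixel_size_um = pixel_size_um,
            z_step_um = z_step_um, time_s = time_s)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d x %d px, %d slices, %.3g um/px, %.3g um z-step\n",
              d[1], d[2], d[3], attr(x, "pixel_size_um"), attr(x, "z_step_um")))
  invisible(x)
}

n_slices <- function(stack) dim(stack)[3]

#' Background estimate from the lowest focal plane
#'
#' Mean intensity of the deepest slice of the stack, used as the background
#' for whole-stack intensity time courses where the lowest plane carries no
#' specific signal.
#'
#' @param stack an [image_stack()].
#' @return scalar background level (a.u.).
#' @export
background_lowest_plane <- function(stack) {
  if (length(stack) == 0) ap_stop("empty stack", "empty_input")
  mean(stack[, , n_slices(stack)])
}

#' Background estimate as mean minus one SD of the stack
#'
#' Uses the population SD (n denominator); for image-sized voxel counts the
#' distinction from the sample SD is immaterial.
#'
#' @param stack an [image_stack()] (or any numeric array).
#' @return `mean(voxels) - sd(voxels)` (a.u.).
#' @export
background_mean_minus_sd <- function(stack) {
  if (length(stack) == 0) ap_stop("empty stack", "empty_input")
  v <- as.numeric(stack)
  mean(v) - sqrt(mean((v - mean(v))^2))
}

#' Subtract a background level, clamped at zero
#'
#' Voxelwise subtraction of a scalar background; negative results are clamped
#' to zero since negative intensities are non-physical.
#'
#' @param image numeric array or matrix.
#' @param bg scalar background (a.u.).
#' @return object of the same shape with `pmax(image - bg, 0)` values.
#' @export
subtract_background <- function(image, bg) {
  if (!is.finite(bg)) ap_stop("background must be finite", "invalid_parameters")
  out <- pmax(image - bg, 0)
  attributes(out) <- attributes(image)
  out
}

#' Mean projection of the most apical slices
#'
#' Averages the `round(depth_um / z_step_um)` most apical slices (those with
#' the lowest slice index) into a 2D image.
#'
#' @param stack an [image_stack()].
#' @param depth_um axial depth to project, micrometres (default 4).
#' @return numeric matrix `[y, x]`.
#' @export
mean_project_apical <- function(stack, depth_um = 4) {
  zs <- attr(stack, "z_step_um")
  k <- max(1L, as.integer(round(depth_um / zs)))
  if (k > n_slices(stack)) ap_stop("requested depth exceeds the stack", "out_of_range")
  apply(unclass(stack)[, , seq_len(k), drop = FALSE], c(1, 2), mean)
}

#' Normalized intensity time course across embryos
#'
#' Per embryo and time point, the background-corrected mean stack intensity
#' is divided by its value at the initial time point, yielding a fold change
#' of 1 at time zero. Because acquisition times vary slightly between
#' embryos, per-embryo series are linearly interpolated onto a common grid
#' before the across-embryo mean and SD are computed.
#'
#' @param embryos a named list with one element per embryo; each element is
#'   either a list of [image_stack()]s (each carrying its `time_s`), or a
#'   data frame with columns `time_s` and `value` holding already measured
#'   background-corrected mean intensities.
#' @param bg_rule background rule for stack input: `"lowest_plane"`
#'   ([background_lowest_plane()]) or `"mean_minus_sd"`
#'   ([background_mean_minus_sd()]).
#' @param grid_times_s optional common time grid; defaults to a uniform grid
#'   over the time range shared by all embryos, with the median sampling
#'   interval.
#' @return A list of class `intensity_timecourse`: `times_s`, `per_embryo`
#'   (matrix of fold changes, one column per embryo), `mean`, `sd`.
#' @export
intensity_timecourse <- function(embryos, bg_rule = c("lowest_plane", "mean_minus_sd"),
                                 grid_times_s = NULL) {
  bg_rule <- match.arg(bg_rule)
  if (length(embryos) == 0) ap_stop("no embryos given", "empty_input")
  series <- lapply(embryos, function(e) {
    if (is.data.frame(e)) {
      data.frame(time_s = e$time_s, value = e$value)
    } else {
      bgf <- if (bg_rule == "lowest_plane") background_lowest_plane else background_mean_minus_sd
      data.frame(time_s = vapply(e, function(s) attr(s, "time_s"), numeric(1)),
                 value = vapply(e, function(s) mean(s) - bgf(s), numeric(1)))
    }
  })
  for (s in series) if (nrow(s) < 2) ap_stop("need at least two time points per embryo", "too_short")
  folds <- lapply(series, function(s) {
    s <- s[order(s$time_s), ]
    if (s$value[1] <= 0) ap_stop("initial intensity must be positive for normalization",
                                 "degenerate_normalization")
    data.frame(time_s = s$time_s, fold = s$value / s$value[1])
  })
  if (is.null(grid_times_s)) {
    lo <- max(vapply(folds, function(s) min(s$time_s), numeric(1)))
    hi <- min(vapply(folds, function(s) max(s$time_s), numeric(1)))
    dt <- stats::median(unlist(lapply(folds, function(s) diff(s$time_s))))
    grid_times_s <- seq(lo, hi, by = dt)
  }
  per <- vapply(folds, function(s) stats::approx(s$time_s, s$fold, xout = grid_times_s)$y,
                numeric(length(grid_times_s)))
  per <- matrix(per, nrow = length(grid_times_s),
                dimnames = list(NULL, names(embryos)))
  structure(list(times_s = grid_times_s, per_embryo = per,
                 mean = rowMeans(per),
                 sd = apply(per, 1, function(v) if (length(v) > 1) stats::sd(v) else 0)),
            class = "intensity_timecourse")
}

#' Mean intensity of each labelled cell
#'
#' @param projection numeric matrix (e.g. a surface or apical projection).
#' @param labels integer matrix of the same shape; 0 is background, positive
#'   integers are cell ids (regions need not be connected).
#' @return named numeric vector mapping each label present in the image to
#'   its mean intensity.
#' @export
per_cell_mean_intensity <- function(projection, labels) {
  if (!all(dim(projection) == dim(labels)))
    ap_stop("projection and labels must have identical shape", "invalid_parameters")
  fg <- labels > 0
  vals <- tapply(projection[fg], labels[fg], mean)
  out <- as.numeric(vals)
  names(out) <- names(vals)
  out
}

#' Area and anisotropy of labelled cells
#'
#' Area is the pixel count scaled by the squared pixel size. Anisotropy is
#' the ratio of the cell's second-moment extent along the anteroposterior
#' (A-P) image axis to that along the orthogonal dorsoventral (D-V) axis,
#' computed from per-pixel coordinate variances with the continuous-pixel
#' correction (+1/12 per axis, each pixel treated as a unit square); for an
#' axis-aligned rectangle this equals the side ratio exactly. Values above 1
#' mean A-P elongated.
#'
#' @param labels integer label matrix, 0 = background.
#' @param pixel_size_um lateral pixel size, micrometres.
#' @param ap_axis which image axis is anteroposterior: `"x"` (columns,
#'   default) or `"y"` (rows).
#' @return data frame with `label`, `area_um2`, `anisotropy`.
#' @export
cell_geometry <- function(labels, pixel_size_um, ap_axis = c("x", "y")) {
  ap_axis <- match.arg(ap_axis)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) ap_stop("no labelled cells", "empty_input")
  res <- lapply(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    n <- nrow(px)
    vy <- mean((px[, 1] - mean(px[, 1]))^2) + 1 / 12
    vx <- mean((px[, 2] - mean(px[, 2]))^2) + 1 / 12
    aniso <- if (ap_axis == "x") sqrt(vx / vy) else sqrt(vy / vx)
    data.frame(label = id, area_um2 = n * pixel_size_um^2, anisotropy = aniso)
  })
  do.call(rbind, res)
}

#' Pearson colocalization of two images
#'
#' Pearson correlation coefficient of two equally shaped images over an
#' optional mask, as used for colocalization analysis of two fluorescence
#' channels.
#'
#' @param img_a,img_b numeric matrices/arrays of identical shape.
#' @param mask optional logical matrix selecting the pixels to correlate.
#' @return scalar correlation in `[-1, 1]`.
#' @export
pearson_colocalization <- function(img_a, img_b, mask = NULL) {
  if (!all(dim(img_a) == dim(img_b))) ap_stop("images must have identical shape", "invalid_parameters")
  a <- as.numeric(img_a); b <- as.numeric(img_b)
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
    ap_stop("correlation undefined: fewer than 2 pixels or zero variance", "undefined_correlation")
  stats::cor(a, b)
}
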