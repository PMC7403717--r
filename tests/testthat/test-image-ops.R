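mk_stack <- function(vox, px = 0.2, zs = 0.5) image_stack(vox, px, zs)

test_that("background rules match their defining formulas", {
  u <- mk_stack(array(7, c(4, 4, 3)))
  expect_equal(background_lowest_plane(u), 7)
  expect_equal(background_mean_minus_sd(u), 7)

  v <- array(10, c(4, 4, 3)); v[, , 3] <- 2    # slice 3 is the lowest plane
  expect_equal(background_lowest_plane(mk_stack(v)), 2)

  two <- mk_stack(array(c(0, 2), c(2, 1, 1)))
  expect_equal(background_mean_minus_sd(two), 0)

  set.seed(3)
  r <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  expect_equal(background_lowest_plane(mk_stack(r)), mean(r[, , 6]))
  n <- length(r)
  expect_equal(background_mean_minus_sd(mk_stack(r)),
               mean(r) - sd(r) * sqrt((n - 1) / n))
})

test_that("background subtraction clamps at zero and preserves shape", {
  img <- matrix(5, 3, 3)
  expect_equal(subtract_background(img, 0), img)
  expect_equal(subtract_background(img, 2), matrix(3, 3, 3))
  expect_equal(subtract_background(matrix(1, 2, 2), 2), matrix(0, 2, 2))
})

test_that("apical mean projection averages the most apical slices", {
  v <- array(0, c(2, 2, 4))
  for (s in 1:4) v[, , s] <- s * 2
  st <- mk_stack(v, zs = 1)
  expect_equal(mean_project_apical(st, depth_um = 1), matrix(2, 2, 2))
  expect_equal(mean_project_apical(st, depth_um = 2), matrix(3, 2, 2))
  set.seed(4)
  r <- array(rnorm(3 * 3 * 5), c(3, 3, 5))
  expect_equal(mean_project_apical(mk_stack(r, zs = 1), depth_um = 3),
               apply(r[, , 1:3], c(1, 2), mean))
  expect_error(mean_project_apical(st, depth_um = 9), class = "ap_out_of_range")
})

test_that("intensity time course normalizes to the initial point and interpolates", {
  const <- list(e1 = data.frame(time_s = c(0, 10, 20), value = c(8, 8, 8)),
                e2 = data.frame(time_s = c(0, 11, 21), value = c(3, 3, 3)))
  tc <- intensity_timecourse(const)
  expect_true(all(abs(tc$mean - 1) < 1e-12))

  pair <- list(e1 = data.frame(time_s = c(0, 10), value = c(10, 17)))
  expect_equal(intensity_timecourse(pair)$per_embryo[, 1], c(1, 1.7))

  # three embryos rising linearly to 2x on jittered grids recover the line
  set.seed(9)
  emb <- lapply(1:3, function(i) {
    t <- sort(c(0, runif(18, 1, 99), 100))
    data.frame(time_s = t, value = 6 * (1 + t / 100))
  })
  names(emb) <- paste0("e", 1:3)
  tc3 <- intensity_timecourse(emb)
  expect_lt(max(abs(tc3$mean - (1 + tc3$times_s / 100))), 0.01)

  bad <- list(e1 = data.frame(time_s = c(0, 5), value = c(0, 4)))
  expect_error(intensity_timecourse(bad), class = "ap_degenerate_normalization")
})

test_that("per-cell mean intensity matches the per-label oracle", {
  lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L; lab[3:4, 3:4] <- 2L
  img <- matrix(10, 4, 4); img[3:4, 3:4] <- 20
  expect_equal(per_cell_mean_intensity(img, lab), c("1" = 10, "2" = 20))
  expect_equal(per_cell_mean_intensity(matrix(7, 4, 4), lab), c("1" = 7, "2" = 7))
  set.seed(5)
  ri <- matrix(rnorm(64), 8, 8)
  rl <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  got <- per_cell_mean_intensity(ri, rl)
  for (id in sort(unique(rl[rl > 0])))
    expect_equal(unname(got[as.character(id)]), mean(ri[rl == id]))
})

test_that("cell geometry gives exact areas and side-ratio anisotropy", {
  sq <- matrix(0L, 20, 20); sq[5:14, 5:14] <- 1L
  g <- cell_geometry(sq, pixel_size_um = 0.5)
  expect_equal(g$area_um2, 25)
  expect_equal(g$anisotropy, 1)

  rect <- matrix(0L, 30, 30); rect[6:15, 6:25] <- 1L   # 10 rows x 20 cols
  ga <- cell_geometry(rect, 0.5, ap_axis = "x")
  expect_equal(ga$anisotropy, 2)
  gb <- cell_geometry(t(rect), 0.5, ap_axis = "x")
  expect_equal(gb$anisotropy, 0.5)
  # transposing the labels exactly inverts anisotropy
  expect_equal(ga$anisotropy * gb$anisotropy, 1)
})

test_that("Pearson colocalization hits the exact and sampling bounds", {
  set.seed(8)
  a <- matrix(rnorm(100), 10, 10)
  expect_equal(pearson_colocalization(a, a), 1)
  expect_equal(pearson_colocalization(a, -a + 5), -1)
  big_a <- matrix(rnorm(1e4), 100, 100)
  big_b <- matrix(rnorm(1e4), 100, 100)
  expect_lt(abs(pearson_colocalization(big_a, big_b)), 0.05)
  mask <- a > 0
  expect_equal(pearson_colocalization(a, a * 2 + 1, mask), 1)
  expect_error(pearson_colocalization(matrix(1, 3, 3), a[1:3, 1:3]),
               class = "ap_undefined_correlation")
})

test_that("labelled movies realize prescribed intensities and areas", {
  p <- labeled_movie_params(n_cells = 2, n_frames = 3, areas_px = 64,
                            intensities = c(10, 20))
  mv <- gen_labeled_movie(p)
  means <- per_cell_mean_intensity(mv$intensity[, , 1], mv$labels[, , 1])
  expect_equal(means, c("1" = 10, "2" = 20))

  # a linear area decrease yields monotone non-increasing pixel areas
  areas <- matrix(seq(120, 40, length.out = 6), 6, 1)
  p2 <- labeled_movie_params(n_cells = 1, n_frames = 6, areas_px = areas,
                             intensities = 5)
  mv2 <- gen_labeled_movie(p2)
  realized <- sapply(1:6, function(f) sum(mv2$labels[, , f] == 1))
  expect_true(all(diff(realized) <= 0))
  expect_true(all(abs(realized - areas[, 1]) <= p2$cell_width_px))

  # determinism and infeasible layout
  p3 <- labeled_movie_params(n_cells = 3, noise_sd = 1, seed = 2)
  expect_identical(gen_labeled_movie(p3), gen_labeled_movie(p3))
  expect_error(gen_labeled_movie(labeled_movie_params(n_cells = 100, frame_shape = c(16, 16))),
               class = "ap_layout_infeasible")
})

test_that("surface phantoms are deterministic with a bright band at the truth", {
  pp <- surface_phantom_params(height_function = "flat", height_args = list(z0 = 5),
                               surface_thickness_slices = 1)
  ph <- gen_surface_phantom(pp)
  expect_true(all(ph$heights_px == 5))
  sums <- apply(unclass(ph$stack), 3, sum)
  expect_equal(which.max(sums), 5)

  tilt <- gen_surface_phantom(surface_phantom_params(
    height_function = "tilted_plane", height_args = list(z0 = 2, slope_x = 0.05)))
  # per-column brightest slice equals the rounded plane height
  vox <- unclass(tilt$stack)
  for (x in c(1, 20, 40, 64)) {
    zprof <- apply(vox[, x, ], 2, sum)
    expect_equal(which.max(zprof), round(tilt$heights_px[1, x]))
  }

  noisy <- surface_phantom_params(height_function = "sinusoid",
                                  height_args = list(z0 = 6, amplitude = 1.5),
                                  noise_sd = 4, seed = 9)
  expect_identical(gen_surface_phantom(noisy), gen_surface_phantom(noisy))
  expect_error(gen_surface_phantom(surface_phantom_params(
    height_function = "flat", height_args = list(z0 = 40))), class = "ap_invalid_parameters")
})
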