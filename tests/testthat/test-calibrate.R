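test_that("planted beads are detected at their true positions", {
  fix <- bead_fixture(seed = 5, noise = FALSE)
  ctr <- detect_beads(fix$stack, min_separation_um = 20)
  expect_equal(nrow(ctr), 10)
  err <- vapply(seq_len(10), function(k) {
    min(sqrt((ctr$x - fix$phantom$beads$x[k])^2 +
               (ctr$y - fix$phantom$beads$y[k])^2 +
               (ctr$z - fix$phantom$beads$z[k])^2))
  }, numeric(1))
  expect_lt(max(err), 2) # within one (axial) voxel

  # empty stack errors
  blank <- array(5, dim = c(20, 20, 5))
  attr(blank, "z_positions_um") <- seq(0, 8, 2)
  attr(blank, "pixel_size_um") <- 1
  expect_error(detect_beads(blank, 10), "no beads")

  expect_error(detect_beads(array(0, c(5, 5, 2)), 5), "3 slices")
})

test_that("beads closer than the separation merge into one detection", {
  ph <- generate_bead_phantom(1, c(60, 60, 60), min_separation_um = 10,
                              seed = 1)
  ph$beads <- tibble::tibble(
    x = c(25, 33), y = 30, z = 30, diameter_um = 4, amplitude = 1)
  oc <- optical_config(pixel_size_um = 0.5, fov_mm = c(0.06, 0.06),
                       gain = 25)
  st <- render_reference_stack(ph, oc, seq(0, 60, 2))
  expect_warning(ctr <- detect_beads(st, min_separation_um = 15), "merged")
  expect_equal(nrow(ctr), 1)
})

test_that("Gaussian profiles are fitted with the exact FWHM ratio", {
  # analytic Gaussian bead: FWHM = 2*sqrt(2*log(2)) * sigma exactly
  pix <- 1; sz <- 2
  xs <- (1:41 - 0.5) * pix
  zs <- seq(0, 40, sz)
  sig <- c(x = 3, y = 4, z = 6)
  ctr0 <- c(x = 20.5, y = 20.5, z = 20)
  st <- array(0, dim = c(41, 41, length(zs)))
  for (k in seq_along(zs)) {
    st[, , k] <- 10 + 100 * exp(
      -outer((xs - ctr0["y"])^2 / (2 * sig["y"]^2),
             (xs - ctr0["x"])^2 / (2 * sig["x"]^2), `+`)
      - (zs[k] - ctr0["z"])^2 / (2 * sig["z"]^2))
  }
  attr(st, "z_positions_um") <- zs
  attr(st, "pixel_size_um") <- pix
  pp <- profile_psf(st, tibble::tibble(x = 20.5, y = 20.5, z = 20))
  ratio <- pp$fwhm_um / pp$sigma_um
  expect_true(all(abs(ratio - 2 * sqrt(2 * log(2))) < 1e-5))
  expect_equal(pp$sigma_um, unname(sig[c("x", "y", "z")]),
               tolerance = 0.02)

  # single bright voxel: under-sampled, tiny FWHM, warning
  delta <- array(0, dim = c(21, 21, 11))
  delta[11, 11, 6] <- 100
  attr(delta, "z_positions_um") <- seq(0, 20, 2)
  attr(delta, "pixel_size_um") <- 1
  w <- capture_warnings(
    pd <- profile_psf(delta, tibble::tibble(x = 10.5, y = 10.5, z = 10)))
  expect_true(any(grepl("under-sampled", w)))
  expect_lt(pd$fwhm_um[pd$axis == "x"], 2)
})

test_that("simulated bead stacks recover the bead-convolved FWHM", {
  fix <- bead_fixture(seed = 5, noise = TRUE)
  ctr <- suppressWarnings(detect_beads(fix$stack, min_separation_um = 20))
  pp <- profile_psf(fix$stack, ctr)
  oc <- optical_config(pixel_size_um = 0.5, fov_mm = c(0.2, 0.2))
  s <- oc$psf_sigma_um
  truth_x <- sphere_gaussian_fwhm(2, s["x"], s["y"], s["z"])
  truth_y <- sphere_gaussian_fwhm(2, s["y"], s["x"], s["z"])
  truth_z <- sphere_gaussian_fwhm(2, s["z"], s["x"], s["y"])
  got <- setNames(pp$fwhm_um, pp$axis)
  expect_lt(abs(got["x"] - truth_x) / truth_x, 0.05)
  expect_lt(abs(got["y"] - truth_y) / truth_y, 0.05)
  expect_lt(abs(got["z"] - truth_z) / truth_z, 0.05)
})

test_that("the 1/e depth is exact on exact exponential data", {
  set.seed(2)
  tab <- tibble::tibble(depth_um = runif(200, 0, 60))
  tab$intensity <- 150 * exp(-tab$depth_um / 20)
  fit <- estimate_sectioning_thickness(tab)
  expect_false(fit$failed)
  # exact up to median interpolation in even-count bins
  expect_equal(fit$d_hat_um, 20, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999)

  # invariance to global intensity scaling
  fit10 <- estimate_sectioning_thickness(
    dplyr::mutate(tab, intensity = intensity * 10))
  expect_equal(fit10$d_hat_um, fit$d_hat_um, tolerance = 1e-9)

  # nonlinear refinement agrees on clean data
  fitn <- estimate_sectioning_thickness(tab, nonlinear = TRUE)
  expect_equal(fitn$d_hat_nls_um, 20, tolerance = 1e-3)

  # constant intensities: failure flag, d undefined
  flat <- tibble::tibble(depth_um = runif(100, 0, 40), intensity = 50)
  ff <- estimate_sectioning_thickness(flat)
  expect_true(ff$failed)
  expect_true(is.na(ff$d_hat_um))

  expect_error(estimate_sectioning_thickness(tab[1:10, ]), "at least 30")
  narrow <- tibble::tibble(depth_um = runif(50, 0, 1.9),
                           intensity = runif(50, 10, 20))
  expect_error(estimate_sectioning_thickness(narrow), "3 usable")
})

test_that("rendered phantoms recover the attenuation depth within 10%", {
  d_hats <- vapply(1:3, function(s) {
    fit <- estimate_sectioning_thickness(sectioning_fixture(15, seed = s))
    fit$d_hat_um
  }, numeric(1))
  expect_lt(abs(median(d_hats) - 15) / 15, 0.10)
})

test_that("cell depths are read off the reference stack", {
  cells <- tibble::tibble(x = c(40, 100, 160), y = 100, z = c(0.5, 10, 24))
  ph <- planted_phantom(cells)
  oc <- small_optics()
  stk <- render_reference_stack(ph, oc, seq(0, 30, 2), axial_sigma_um = 2)
  bf <- render_block_face(ph, oc, noise = FALSE, quantize = FALSE)
  seg <- segment_cells(bf, pixel_size_um = 2)
  dep <- assign_cell_depths(seg$labels, stk)
  got <- dep[order(match(dep$label, seg$cells$label)), ]
  # match each segment to its planted cell by x
  ord <- order(seg$cells$x_um)
  depths <- dep$depth_um[match(seg$cells$label[ord], dep$label)]
  expect_equal(length(depths), 3)
  expect_lte(abs(depths[1] - 0.5), 2)   # surface cell -> first slices
  expect_lte(abs(depths[2] - 10), 2)
  expect_lte(abs(depths[3] - 24), 2)

  # a background-only mask is excluded
  labs <- seg$labels
  labs[1:3, 1:3] <- max(labs) + 1L
  dep2 <- assign_cell_depths(labs, stk)
  expect_true(dep2$excluded[dep2$label == max(labs)])
})

test_that("correlation profiles peak at the shallow slices and decay", {
  fix <- correlation_fixture(d_um = 20, seed = 2)
  prof <- correlation_vs_depth(fix$surface, fix$stack)
  expect_s3_class(prof, "depth_correlation")
  expect_true(all(prof$r >= -1 & prof$r <= 1, na.rm = TRUE))
  expect_lte(prof$depth_um[which.max(prof$r)], 4)
  beyond <- prof$r[prof$depth_um >= 20]
  # non-increasing up to the numerical floor of the deep-slice residuals
  expect_true(all(diff(beyond) <= 5e-3))

  # slice identical to the surface image correlates perfectly
  s <- image_channel(fix$surface, "R")
  noise_slice <- withr::with_seed(6, matrix(runif(length(s), 0, 50),
                                            nrow(s)))
  st2 <- array(c(s, noise_slice), dim = c(dim(s), 2))
  attr(st2, "z_positions_um") <- c(0, 2)
  attr(st2, "pixel_size_um") <- 2
  p2 <- correlation_vs_depth(fix$surface, st2)
  expect_equal(p2$r[1], 1, tolerance = 1e-12)
  expect_lt(abs(p2$r[2]), 0.1) # uncorrelated noise slice
})
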