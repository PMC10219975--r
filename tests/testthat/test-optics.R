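test_that("Beer-Lambert depth weight matches the closed form", {
  expect_equal(depth_weight(0, 20), 1)
  expect_equal(depth_weight(20, 20), exp(-1))
  expect_equal(depth_weight(40, 20), exp(-2))
  z <- seq(0, 100, 5)
  expect_true(all(diff(depth_weight(z, 20)) < 0))
  expect_error(depth_weight(-1, 20), "negative depth")
  expect_error(depth_weight(5, 0), "positive")
})

test_that("spectral mixing matrix maps dyes to sensible channels", {
  m <- spectral_mixing_matrix()
  expect_equal(colSums(m), c(hoechst = 1, pi = 1, af594 = 1))
  expect_true(all(m >= 0))
  # PI-like (659 nm) red-dominant; Hoechst-like (496 nm) in green/blue
  expect_gt(m["R", "pi"], 0.9)
  expect_gt(m["G", "hoechst"] + m["B", "hoechst"], 0.9)
  # AF594-like red with some green crosstalk
  expect_gt(m["R", "af594"], m["G", "af594"])
  expect_gt(m["G", "af594"], 0.01)
})

test_that("apply_mixing is a per-pixel linear map", {
  a <- matrix(2, 4, 5); b <- matrix(3, 4, 5); c0 <- matrix(1, 4, 5)
  out <- apply_mixing(list(a, b, c0), diag(3))
  expect_equal(out[, , 1], a)
  expect_equal(out[, , 3], c0)
  out2 <- apply_mixing(list(a), matrix(c(0, 0, 1), ncol = 1))
  expect_true(all(out2[, , 1:2] == 0))
  expect_equal(out2[, , 3], a)
  M <- matrix(c(0.5, 0.2, 0, 0.1, 0.7, 0.3), nrow = 3)
  out3 <- apply_mixing(list(a, b), M)
  expected <- M %*% c(2, 3) # constant-image matrix-product oracle
  for (ch in 1:3) expect_equal(unique(as.numeric(out3[, , ch])), expected[ch])
  expect_error(apply_mixing(list(a, b), diag(3)), "per mixing-matrix column")
})

test_that("empty scenes render to background only", {
  reg <- region_model(1, "empty", c(0, 200), c(0, 200), c(0, 50), 0)
  ph <- generate_tissue_phantom(c(200, 200, 50), reg, seed = 1)
  oc <- small_optics()
  img <- render_block_face(ph, oc, seed = 4)
  expect_true(all(img <= oc$noise$offset + 5 * oc$noise$read_sd))
})

test_that("noiseless intensity falls by e per attenuation depth", {
  oc <- small_optics()
  d <- oc$attenuation_depth_um
  # fully submerged identical cells one attenuation depth apart
  i1 <- render_block_face(planted_phantom(one_cell(z = 8)), oc,
                          noise = FALSE, quantize = FALSE)
  i2 <- render_block_face(planted_phantom(one_cell(z = 8 + d)), oc,
                          noise = FALSE, quantize = FALSE)
  off <- oc$noise$offset
  ratio <- (sum(i1) - off * length(i1)) / (sum(i2) - off * length(i2))
  expect_lt(abs(ratio - exp(1)) / exp(1), 0.01)

  # a cell five depths down is invisible next to a surface cell (a cell
  # touching the face from below, z = soma radius)
  isurf <- render_block_face(planted_phantom(one_cell(z = 5)), oc,
                             noise = FALSE, quantize = FALSE)
  i5 <- render_block_face(planted_phantom(one_cell(z = 5 * d)), oc,
                          noise = FALSE, quantize = FALSE)
  expect_lt(max(i5 - off), 0.01 * max(isurf - off))
})

test_that("noiseless rendering is linear and monotone in depth", {
  oc <- small_optics()
  a <- planted_phantom(one_cell(x = 60, y = 60, z = 8))
  b <- planted_phantom(one_cell(x = 140, y = 140, z = 12))
  ab <- planted_phantom(dplyr::bind_rows(one_cell(60, 60, 8),
                                         one_cell(140, 140, 12)))
  ra <- render_block_face(a, oc, noise = FALSE, quantize = FALSE)
  rb <- render_block_face(b, oc, noise = FALSE, quantize = FALSE)
  rab <- render_block_face(ab, oc, noise = FALSE, quantize = FALSE)
  off <- oc$noise$offset
  expect_equal(unclass(rab) - off,
               (unclass(ra) - off) + (unclass(rb) - off),
               tolerance = 1e-10)

  depths <- c(6, 10, 16, 24, 40)
  sums <- vapply(depths, function(z) {
    img <- render_block_face(planted_phantom(one_cell(z = z)), oc,
                             noise = FALSE, quantize = FALSE)
    sum(img - off)
  }, numeric(1))
  expect_true(all(diff(sums) < 0))
})

test_that("noise is seeded and independent across seeds", {
  reg <- region_model(1, "empty", c(0, 200), c(0, 200), c(0, 50), 0)
  ph <- generate_tissue_phantom(c(200, 200, 50), reg, seed = 1)
  oc <- small_optics()
  i1 <- render_block_face(ph, oc, seed = 11)
  i2 <- render_block_face(ph, oc, seed = 11)
  i3 <- render_block_face(ph, oc, seed = 12)
  expect_identical(unclass(i1), unclass(i2))
  expect_false(identical(unclass(i1), unclass(i3)))
  expect_lt(abs(cor(as.numeric(i1), as.numeric(i3))), 0.05)
})

test_that("reference stacks localise cells axially", {
  ph <- planted_phantom(one_cell(z = 10))
  oc <- small_optics()
  st <- render_reference_stack(ph, oc, seq(0, 30, 2), axial_sigma_um = 2)
  brightest <- which.max(apply(st, 3, max))
  expect_equal(attr(st, "z_positions_um")[brightest], 10)

  # surface-confined scene: block-face and surface slice agree
  ph2 <- planted_phantom(one_cell(z = 6))
  bf <- render_block_face(ph2, oc, noise = FALSE, quantize = FALSE)
  st2 <- render_reference_stack(ph2, oc, c(0, 2, 4, 6))
  expect_gt(cor(as.numeric(image_channel(bf, "R")),
                as.numeric(st2[, , 4])), 0.99)

  expect_error(render_reference_stack(ph, oc, numeric(0)), "non-empty")
  expect_error(render_reference_stack(ph, oc, c(4, 2)), "ascending")
})

test_that("out-of-bounds tiles warn and render background", {
  ph <- planted_phantom(one_cell())
  oc <- small_optics()
  expect_warning(
    img <- render_block_face(ph, oc, tile_origin_um = c(5000, 5000),
                             seed = 1),
    "outside")
  expect_true(all(img <= oc$noise$offset + 5 * oc$noise$read_sd))
})
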