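# Shared fixture builders for the test suite.

# Phantom with an explicit hand-placed cell table (bypasses the random
# generator; used to plant known ground truth).
planted_phantom <- function(cells, box_um = c(200, 200, 200),
                            regions = NULL) {
  if (is.null(regions)) {
    regions <- region_model(1, "bulk", c(0, box_um[1]), c(0, box_um[2]),
                            c(0, box_um[3]), 0)
  }
  ph <- generate_tissue_phantom(box_um, regions, seed = 0)
  defaults <- tibble::tibble(
    nucleus_radius = 3, soma_radius = 5,
    amp_hoechst = 1, amp_pi = 1, amp_af594 = 0, region_id = 1L
  )
  for (col in names(defaults)) {
    if (!col %in% names(cells)) cells[[col]] <- defaults[[col]]
  }
  if (!"cell_id" %in% names(cells)) cells$cell_id <- seq_len(nrow(cells))
  ph$cells <- cells
  ph
}

small_optics <- function(...) {
  optical_config(fov_mm = c(0.2, 0.2), gain = 25, ...)
}

# Single PI-labelled cell at a given position.
one_cell <- function(x = 100, y = 100, z = 8) {
  tibble::tibble(x = x, y = y, z = z)
}

# Brute-force tile-count oracle: smallest n with (n-1)*stride + fov
# covering the extent, found by enumeration.
brute_force_tile_count <- function(extent, fov, overlap) {
  if (extent <= fov) return(1L)
  stride <- fov * (1 - overlap)
  n <- 1L
  while ((n - 1) * stride + fov < extent - 1e-12) n <- n + 1L
  n
}

# Quadrature oracle for the image of a uniform fluorescent sphere under a
# separable Gaussian PSF: 1D profile through the centre along one axis,
# FWHM by half-maximum crossing on a fine grid.
sphere_gaussian_fwhm <- function(R, sigma_along, sigma_perp1, sigma_perp2,
                                 step = 0.2, grid_step = 0.02) {
  g <- seq(-R, R, step)
  vox <- expand.grid(a = g, b = g, c = g)
  vox <- vox[vox$a^2 + vox$b^2 + vox$c^2 <= R^2, ]
  ts <- seq(-4 * sigma_along - R, 4 * sigma_along + R, grid_step)
  prof <- vapply(ts, function(t) {
    sum(exp(-((t - vox$a)^2) / (2 * sigma_along^2)
            - (vox$b^2) / (2 * sigma_perp1^2)
            - (vox$c^2) / (2 * sigma_perp2^2)))
  }, numeric(1))
  half <- max(prof) / 2
  diff(range(ts[prof >= half]))
}

# Cut a window out of a larger rendered image as a pseudo-tile.
cut_tile <- function(full, x_mm, y_mm, fov_px, pixel_size_um = 2) {
  i0 <- round(x_mm * 1000 / pixel_size_um)
  j0 <- round(y_mm * 1000 / pixel_size_um)
  t <- unclass(full)[(j0 + 1):(j0 + fov_px[2]),
                     (i0 + 1):(i0 + fov_px[1]), , drop = FALSE]
  attr(t, "pixel_size_um") <- pixel_size_um
  attr(t, "bit_depth") <- 8L
  t
}

# A textured synthetic section used by the stitching tests.
textured_section <- function(seed = 3, fov_mm = c(0.6, 0.4)) {
  reg <- region_model(1, "A", c(0, fov_mm[1] * 1000),
                      c(0, fov_mm[2] * 1000), c(0, 40), 15000)
  ph <- generate_tissue_phantom(c(fov_mm * 1000, 40), reg, seed = seed)
  oc <- optical_config(fov_mm = fov_mm, gain = 25)
  render_block_face(ph, oc, seed = seed + 100)
}
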