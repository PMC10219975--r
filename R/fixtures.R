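# Canonical synthetic study conditions. These constructors freeze the
# simulated experiments the package's validation is built around; they
# are first-class generator code, not test scaffolding.

#' Two-region habenula-like experiment configuration
#'
#' A medial/lateral habenula-style pair: two abutting 300 x 400 um
#' regions with a 2:1 cell-density contrast (12000 vs 6000 cells/mm3 —
#' densities for mouse MHb/LHb are not established in the literature, so
#' these are fixture choices, sparse enough at the simulated resolution
#' for automated segmentation to stand in for manual counting), imaged as
#' 10 serial 50 um sections of an 800 x 600 x 520 um block in a single
#' 0.8 x 0.6 mm field.
#'
#' @param seed root seed for the run.
#' @param density_high,density_low region densities in cells/mm3.
#' @return A validated `experiment_config` for [run_pipeline()].
#' @export
habenula_fixture_config <- function(seed, density_high = 12000,
                                    density_low = 6000) {
  validate_config(list(
    seed = seed,
    phantom = list(
      box_um = c(800, 600, 520),
      regions = list(
        list(region_id = 1, name = "MHb-like", xlim = c(100, 400),
             ylim = c(100, 500), zlim = c(0, 520),
             density_per_mm3 = density_high),
        list(region_id = 2, name = "LHb-like", xlim = c(400, 700),
             ylim = c(100, 500), zlim = c(0, 520),
             density_per_mm3 = density_low)
      )
    ),
    optics = list(fov_mm = c(0.8, 0.6), gain = 25),
    sections = list(thickness_um = 50),
    quantify = list(compare_regions = c(1, 2))
  ))
}

#' Sectioning-thickness recovery fixture
#'
#' Renders one block face of a phantom whose ~600 cells sit at uniform
#' depths over (soma radius, 2d]; fully submerged cells make the per-cell
#' intensity follow Beer's law exactly, so the 1/e-depth estimator can be
#' validated by parameter recovery. Per-cell intensities are measured on
#' the rendered (noisy, quantised) image at the ground-truth centroids;
#' depths are taken from ground truth, standing in for confocal depth
#' assignment.
#'
#' @param d_um true attenuation depth to render with.
#' @param seed seed for phantom and noise.
#' @param n_cells target expected cell count.
#' @return Tibble (`depth_um`, `intensity`) ready for
#'   [estimate_sectioning_thickness()].
#' @export
sectioning_fixture <- function(d_um, seed, n_cells = 600) {
  z0 <- 8
  zmax <- 2 * d_um + z0
  area_mm2 <- 0.78^2
  reg <- region_model(1, "bulk", c(10, 790), c(10, 790), c(z0, zmax),
                      n_cells / (area_mm2 * (zmax - z0) / 1000))
  ph <- generate_tissue_phantom(c(800, 800, zmax + 20), reg, seed = seed)
  oc <- optical_config(attenuation_depth_um = d_um, fov_mm = c(0.8, 0.8),
                       gain = 25)
  img <- render_block_face(ph, oc, seed = seed + 1)
  ints <- measure_cell_intensities(img, ph$cells)
  tibble::tibble(depth_um = ph$cells$z, intensity = ints$intensity)
}

#' Bead calibration fixture
#'
#' Ten 4 um beads in a 200 x 200 x 120 um agarose-like volume at >= 45 um
#' separation (axial profiles of sd ~14 um must not overlap), imaged as
#' an axial focus scan at 2 um steps with 0.5 um lateral sampling.
#'
#' @param seed seed for placement and noise.
#' @param noise add camera noise?
#' @return List with the `phantom` and the rendered `stack`.
#' @export
bead_fixture <- function(seed, noise = TRUE) {
  ph <- generate_bead_phantom(10, box_um = c(200, 200, 120),
                              min_separation_um = 45, diameter_um = 4,
                              seed = seed)
  oc <- optical_config(pixel_size_um = 0.5, fov_mm = c(0.2, 0.2),
                       gain = 25)
  st <- render_reference_stack(ph, oc, seq(0, 120, 2), noise = noise,
                               quantize = noise, seed = seed + 1)
  list(phantom = ph, stack = st)
}

#' Depth-correlation fixture
#'
#' A cut block face: ~160 cells at uniform depths from just above the
#' face (transected somata) down to 2d, rendered noiselessly, plus a
#' co-registered confocal-like stack (2 um axial sd, 2 um steps).
#'
#' @param d_um attenuation depth.
#' @param seed placement seed.
#' @return List with `phantom`, `surface` (block-face image) and `stack`.
#' @export
correlation_fixture <- function(d_um = 20, seed = 2) {
  reg <- region_model(1, "bulk", c(10, 390), c(10, 390), c(0, 2 * d_um), 1)
  ph <- generate_tissue_phantom(c(400, 400, 3 * d_um), reg, seed = 0)
  n <- 160
  ph$cells <- with_seed(seed, tibble::tibble(
    cell_id = seq_len(n),
    x = runif(n, 10, 390), y = runif(n, 10, 390),
    z = runif(n, -4, 2 * d_um),
    nucleus_radius = 3, soma_radius = 5,
    amp_hoechst = 1, amp_pi = rlnorm(n, -0.3^2 / 2, 0.3), amp_af594 = 0,
    region_id = 1L
  ))
  oc <- optical_config(attenuation_depth_um = d_um, fov_mm = c(0.4, 0.4),
                       gain = 25)
  surface <- render_block_face(ph, oc, noise = FALSE, quantize = FALSE)
  stack <- render_reference_stack(ph, oc, seq(0, 2 * d_um, 2),
                                  axial_sigma_um = 2)
  list(phantom = ph, surface = surface, stack = stack)
}
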