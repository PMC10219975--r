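#' Build a dye-to-RGB spectral mixing matrix
#'
#' Each dye's emission spectrum is idealised as a Gaussian around its
#' emission peak and integrated over idealised camera passbands
#' (R: 580-700, G: 480-580, B: 400-480 nm); columns are normalised to unit
#' sum. With the default peaks this maps the propidium-iodide-like dye
#' (659 nm) to a red-dominant response, the Hoechst-like dye (496 nm) to
#' green/blue, and the AF594-like label (613 nm) to red with a small green
#' crosstalk.
#'
#' @param emission_peaks_nm named numeric vector of dye emission peaks.
#' @param width_nm Gaussian sd of the idealised emission spectrum.
#' @return 3 x n_dyes matrix with rows R, G, B and one column per dye.
#' @export
spectral_mixing_matrix <- function(
    emission_peaks_nm = c(hoechst = 496, pi = 659, af594 = 613),
    width_nm = 35) {
  bands <- list(R = c(580, 700), G = c(480, 580), B = c(400, 480))
  m <- vapply(emission_peaks_nm, function(pk) {
    w <- vapply(bands, function(b) {
      pnorm(b[2], pk, width_nm) - pnorm(b[1], pk, width_nm)
    }, numeric(1))
    if (sum(w) <= 0) w <- c(R = 1, G = 0, B = 0) # out-of-band: clamp to red
    w / sum(w)
  }, numeric(3))
  rownames(m) <- names(bands)
  m
}

#' Forward-model configuration for the DUV microscope
#'
#' Collects every parameter of the virtual instrument. Defaults follow the
#' characterised instrument: 1/e attenuation depth 20 um, field of view
#' ~1.3 x 1.0 mm, 30 ms exposure, ~8.13 mW incident power (metadata only),
#' oblique illumination at 60 degrees modelled as a multiplicative linear
#' ramp plus a radial vignette.
#'
#' @param attenuation_depth_um Beer-Lambert 1/e depth d (um).
#' @param psf_sigma_um Gaussian PSF sigmas, named (x, y, z), in um.
#' @param pixel_size_um lateral sample-plane pixel size (um/px).
#' @param fov_mm field of view (width x, height y) in mm; the pixel grid is
#'   `round(fov_mm * 1000 / pixel_size_um)`.
#' @param illumination list: `ramp_fraction` (+-fractional intensity ramp
#'   across the FOV along x), `vignette` (fractional radial fall-off at the
#'   corners) and `angle_deg` (incidence angle, metadata).
#' @param dye_compartments matrix (n_dyes x 2, columns `nucleus`, `rim`)
#'   giving each dye's weight in the nuclear sphere and the Nissl-like
#'   shell between nucleus and soma radius.
#' @param mixing_matrix 3 x n_dyes dye-to-RGB matrix
#'   (see [spectral_mixing_matrix()]).
#' @param gain digital numbers per unit of depth-integrated emission.
#' @param noise list: `photons_per_dn` (shot-noise scale; Poisson variance
#'   = signal / photons_per_dn), `read_sd` (Gaussian read noise, DN),
#'   `offset` (camera baseline, DN).
#' @param bit_depth 8 or 16.
#' @param exposure_ms,power_mW acquisition metadata (no radiometric model).
#' @return An `optical_config` list.
#' @export
optical_config <- function(attenuation_depth_um = 20,
                           psf_sigma_um = c(x = 1.5, y = 1.53, z = 13.8),
                           pixel_size_um = 2,
                           fov_mm = c(1.3, 1.0),
                           illumination = list(ramp_fraction = 0.15,
                                               vignette = 0.05,
                                               angle_deg = 60),
                           dye_compartments = NULL,
                           mixing_matrix = spectral_mixing_matrix(),
                           gain = 25,
                           noise = list(photons_per_dn = 2, read_sd = 2,
                                        offset = 8),
                           bit_depth = 8,
                           exposure_ms = 30,
                           power_mW = 8.13) {
  stopifnot(attenuation_depth_um > 0, all(psf_sigma_um > 0),
            pixel_size_um > 0, length(fov_mm) == 2, all(fov_mm > 0),
            all(mixing_matrix >= 0), nrow(mixing_matrix) == 3,
            bit_depth %in% c(8, 16), gain > 0)
  dyes <- colnames(mixing_matrix)
  if (is.null(dyes)) dyes <- paste0("dye", seq_len(ncol(mixing_matrix)))
  if (is.null(dye_compartments)) {
    # nuclear stain; nuclear + perikaryal Nissl-like stain; cytoplasmic label
    dye_compartments <- matrix(
      c(1, 0, 1, 1, 0, 1)[seq_len(2 * length(dyes))],
      ncol = 2, byrow = TRUE,
      dimnames = list(dyes, c("nucleus", "rim"))
    )
  }
  structure(list(
    attenuation_depth_um = attenuation_depth_um,
    psf_sigma_um = psf_sigma_um,
    pixel_size_um = pixel_size_um,
    fov_mm = as.numeric(fov_mm),
    fov_px = as.integer(round(fov_mm * 1000 / pixel_size_um)),
    illumination = illumination,
    dyes = dyes,
    dye_compartments = dye_compartments,
    mixing_matrix = mixing_matrix,
    gain = gain,
    noise = noise,
    bit_depth = as.integer(bit_depth),
    exposure_ms = exposure_ms,
    power_mW = power_mW
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> d = %g um, psf sigma (%g, %g, %g) um, %g um/px, fov %d x %d px, %d-bit\n",
    x$attenuation_depth_um, x$psf_sigma_um[1], x$psf_sigma_um[2],
    x$psf_sigma_um[3], x$pixel_size_um, x$fov_px[1], x$fov_px[2],
    x$bit_depth))
  invisible(x)
}

#' Beer-Lambert depth weight
#'
#' Relative excitation/emission weight of material at depth `z_um` below
#' the block face: `exp(-z/d)`, strictly decreasing in z, equal to 1/e at
#' z = d (the optical sectioning thickness).
#'
#' @param z_um depth below the block face (um, >= 0).
#' @param d_um 1/e attenuation depth (um, > 0).
#' @return Weight(s) in (0, 1].
#' @export
depth_weight <- function(z_um, d_um) {
  if (any(d_um <= 0)) abort("attenuation depth must be positive")
  if (any(z_um < 0)) abort("negative depth: material above the block face does not exist")
  exp(-z_um / d_um)
}

#' Mix per-dye emission images into RGB
#'
#' Per-pixel linear combination of dye abundance images through a
#' 3 x n_dyes mixing matrix.
#'
#' @param dye_images list of equal-sized matrices, one per dye.
#' @param mixing_matrix 3 x n_dyes non-negative matrix.
#' @return rows x cols x 3 array.
#' @export
apply_mixing <- function(dye_images, mixing_matrix) {
  if (length(dye_images) != ncol(mixing_matrix)) {
    abort("one dye image per mixing-matrix column required")
  }
  if (nrow(mixing_matrix) != 3) abort("mixing matrix must have 3 rows (R, G, B)")
  dims <- dim(dye_images[[1]])
  if (!all(vapply(dye_images, function(m) identical(dim(m), dims), logical(1)))) {
    abort("dye images must share one shape")
  }
  out <- array(0, dim = c(dims, 3))
  for (ch in 1:3) {
    acc <- matrix(0, dims[1], dims[2])
    for (d in seq_along(dye_images)) {
      acc <- acc + mixing_matrix[ch, d] * dye_images[[d]]
    }
    out[, , ch] <- acc
  }
  out
}

# Multiplicative illumination field for a pixel grid: linear ramp along x
# (oblique side illumination) times a radial vignette.
illumination_field <- function(width_px, height_px, illumination) {
  xn <- (seq_len(width_px) - 0.5) / width_px   # 0..1
  yn <- (seq_len(height_px) - 0.5) / height_px
  ramp <- 1 + illumination$ramp_fraction * (2 * xn - 1)
  r2 <- outer((yn - 0.5)^2, (xn - 0.5)^2, `+`) / 0.5 # corner ~ 1
  field <- matrix(ramp, nrow = height_px, ncol = width_px, byrow = TRUE)
  field * (1 - illumination$vignette * r2)
}
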