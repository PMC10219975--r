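# Forward rendering: block-face images under Beer-Lambert surface
# excitation, and confocal-like reference z-stacks.

# Exact depth integral of exp(-z/d) along the chord of a sphere of radius
# R centred at depth zc, for squared lateral offsets rho2, clipped to the
# material below the block face (z >= 0). Closed form: d*(e^-a/d - e^-b/d).
chord_beer <- function(rho2, R, zc, d) {
  out <- numeric(length(rho2))
  ok <- rho2 < R^2
  if (!any(ok)) return(out)
  h <- sqrt(R^2 - rho2[ok])
  a <- pmax(0, zc - h)
  b <- zc + h
  v <- d * (exp(-a / d) - exp(-b / d))
  v[b <= a] <- 0
  out[ok] <- v
  out
}

# Same chord geometry under a Gaussian axial sectioning profile centred at
# slice depth zs with sd sz (confocal surrogate; no Beer attenuation).
chord_gauss <- function(rho2, R, zc, zs, sz) {
  out <- numeric(length(rho2))
  ok <- rho2 < R^2
  if (!any(ok)) return(out)
  h <- sqrt(R^2 - rho2[ok])
  a <- pmax(0, zc - h)
  b <- zc + h
  v <- sz * sqrt(2 * pi) * (pnorm(b, zs, sz) - pnorm(a, zs, sz))
  v[b <= a] <- 0
  out[ok] <- v
  out
}

# Separable lateral Gaussian blur with possibly anisotropic sigmas (px).
gaussian_blur_xy <- function(m, sx_px, sy_px) {
  if (max(sx_px, sy_px) < 0.05) return(m)
  half <- max(1L, ceiling(3 * max(sx_px, sy_px)))
  kx <- exp(-((-half:half)^2) / (2 * max(sx_px, 1e-6)^2))
  ky <- exp(-((-half:half)^2) / (2 * max(sy_px, 1e-6)^2))
  k <- outer(ky / sum(ky), kx / sum(kx))
  as.matrix(EBImage::filter2(EBImage::Image(m), k, boundary = 0))
}

# Paint one sphere's chord integral into an accumulator matrix around its
# centre; integral_fun maps squared lateral radius (um^2) to a value.
paint_sphere <- function(acc, cx_um, cy_um, R_um, pix, integral_fun, scale) {
  H <- nrow(acc); W <- ncol(acc)
  i0 <- max(1L, floor((cx_um - R_um) / pix - 1))
  i1 <- min(W, ceiling((cx_um + R_um) / pix + 1))
  j0 <- max(1L, floor((cy_um - R_um) / pix - 1))
  j1 <- min(H, ceiling((cy_um + R_um) / pix + 1))
  if (i0 > i1 || j0 > j1) return(acc)
  xs <- ((i0:i1) - 0.5) * pix - cx_um
  ys <- ((j0:j1) - 0.5) * pix - cy_um
  rho2 <- outer(ys^2, xs^2, `+`)
  vals <- integral_fun(as.numeric(rho2), R_um)
  if (any(vals > 0)) {
    acc[j0:j1, i0:i1] <- acc[j0:j1, i0:i1] +
      scale * matrix(vals, nrow = length(ys))
  }
  acc
}

# Accumulate all cells and beads of a phantom into per-dye emission images
# on a tile's pixel grid; depth_fun(rho2, R, zc) gives the axial integral.
accumulate_emission <- function(phantom, config, tile_origin_um, fov_px,
                                face_z_um, depth_fun, max_depth_um) {
  W <- fov_px[1]; H <- fov_px[2]
  pix <- config$pixel_size_um
  dye_imgs <- lapply(config$dyes, function(d) matrix(0, H, W))
  names(dye_imgs) <- config$dyes
  cells <- phantom$cells
  if (nrow(cells) > 0) {
    zc <- cells$z - face_z_um
    keep <- (zc + cells$soma_radius) > 0 & (zc - cells$soma_radius) < max_depth_um
    pad <- max(cells$soma_radius, 0) + 3 * max(config$psf_sigma_um[1:2])
    cx <- cells$x - tile_origin_um[1]
    cy <- cells$y - tile_origin_um[2]
    keep <- keep & cx > -pad & cx < W * pix + pad &
      cy > -pad & cy < H * pix + pad
    cells <- cells[keep, ]
    zc <- zc[keep]; cx <- cx[keep]; cy <- cy[keep]
    for (k in seq_len(nrow(cells))) {
      rn <- cells$nucleus_radius[k]
      rs <- cells$soma_radius[k]
      f_n <- function(rho2, R) depth_fun(rho2, R, zc[k])
      # nucleus integral and soma integral; rim = soma - nucleus
      for (dy in config$dyes) {
        amp <- cells[[paste0("amp_", dy)]][k]
        if (amp <= 0) next
        wn <- config$dye_compartments[dy, "nucleus"]
        wr <- config$dye_compartments[dy, "rim"]
        if (wn == 0 && wr == 0) next
        if (wr == 0) {
          dye_imgs[[dy]] <- paint_sphere(dye_imgs[[dy]], cx[k], cy[k], rn,
                                         pix, f_n, amp * wn)
        } else {
          dye_imgs[[dy]] <- paint_sphere(dye_imgs[[dy]], cx[k], cy[k], rs,
                                         pix, f_n, amp * wr)
          if (wn != wr) {
            dye_imgs[[dy]] <- paint_sphere(dye_imgs[[dy]], cx[k], cy[k], rn,
                                           pix, f_n, amp * (wn - wr))
          }
        }
      }
    }
  }
  beads <- phantom$beads
  if (nrow(beads) > 0) {
    bz <- beads$z - face_z_um
    for (k in seq_len(nrow(beads))) {
      if (bz[k] + beads$diameter_um[k] / 2 <= 0) next
      f_b <- function(rho2, R) depth_fun(rho2, R, bz[k])
      for (dy in config$dyes) {
        dye_imgs[[dy]] <- paint_sphere(
          dye_imgs[[dy]], beads$x[k] - tile_origin_um[1],
          beads$y[k] - tile_origin_um[2], beads$diameter_um[k] / 2,
          pix, f_b, beads$amplitude[k])
      }
    }
  }
  sx <- config$psf_sigma_um["x"] / pix
  sy <- config$psf_sigma_um["y"] / pix
  lapply(dye_imgs, gaussian_blur_xy, sx_px = sx, sy_px = sy)
}

apply_noise_and_quantize <- function(px, config, noise, quantize, seed) {
  off <- config$noise$offset
  if (noise) {
    px <- with_seed(seed, {
      ppd <- config$noise$photons_per_dn
      shot <- array(rpois(length(px), lambda = pmax(px, 0) * ppd) / ppd,
                    dim = dim(px))
      shot + off + array(rnorm(length(px), 0, config$noise$read_sd),
                         dim = dim(px))
    })
  } else {
    px <- px + off
  }
  if (quantize) px <- quantize(px, config$bit_depth)
  px
}

#' Render a block-face image
#'
#' Forward model of surface-excitation imaging: each cell compartment
#' (nuclear sphere, Nissl-like shell) contributes its exact
#' depth-integrated emission under the Beer-Lambert weight `exp(-z/d)`,
#' clipped at the block face; the per-dye images are blurred with the
#' lateral Gaussian PSF, shaded by the oblique-illumination field, mixed
#' to RGB, scaled by the gain, and optionally degraded with shot + read
#' noise and quantised to the configured bit depth.
#'
#' @param phantom a `tissue_phantom`.
#' @param config an [optical_config()].
#' @param face_z_um depth of the current block face in the phantom frame.
#' @param tile_origin_um lateral (x, y) origin of the tile in um.
#' @param fov_px optional (width, height) override of `config$fov_px`.
#' @param noise add shot and read noise (seeded)?
#' @param quantize clip and round-half-even to the bit-depth range?
#' @param seed RNG seed for the noise draw.
#' @param section_index stored in the image metadata.
#' @return A `blockface_image`: rows x cols x 3 array (row = y, col = x)
#'   with spatial metadata attributes.
#' @export
render_block_face <- function(phantom, config, face_z_um = 0,
                              tile_origin_um = c(0, 0), fov_px = NULL,
                              noise = TRUE, quantize = TRUE, seed = NULL,
                              section_index = NA_integer_) {
  fov_px <- if (is.null(fov_px)) config$fov_px else as.integer(fov_px)
  pix <- config$pixel_size_um
  if (tile_origin_um[1] >= phantom$box_um[1] ||
      tile_origin_um[2] >= phantom$box_um[2] ||
      tile_origin_um[1] + fov_px[1] * pix <= 0 ||
      tile_origin_um[2] + fov_px[2] * pix <= 0) {
    warn("tile lies fully outside the phantom: background-only image")
  }
  d <- config$attenuation_depth_um
  dye_imgs <- accumulate_emission(
    phantom, config, tile_origin_um, fov_px, face_z_um,
    depth_fun = function(rho2, R, zc) chord_beer(rho2, R, zc, d),
    max_depth_um = 6 * d
  )
  field <- illumination_field(fov_px[1], fov_px[2], config$illumination)
  dye_imgs <- lapply(dye_imgs, `*`, field)
  rgb <- apply_mixing(dye_imgs, config$mixing_matrix) * config$gain
  rgb <- apply_noise_and_quantize(rgb, config, noise, quantize, seed)
  new_blockface_image(rgb, tile_origin_um, face_z_um, section_index,
                      pix, if (quantize) config$bit_depth else NA_integer_)
}

#' Render a confocal-like reference z-stack
#'
#' Images each requested plane with Gaussian axial sectioning (sd
#' `psf_sigma_um["z"]`) and the same lateral PSF and pixel grid as
#' [render_block_face()], but with no Beer-Lambert depth attenuation and
#' no illumination shading: the surrogate for a co-registered confocal
#' stack. Output is single-channel (summed dye emission).
#'
#' @inheritParams render_block_face
#' @param z_positions_um ascending plane depths; the conventional spacing
#'   is 2 um.
#' @param axial_sigma_um sd of the Gaussian axial sectioning. The default
#'   (NULL) uses `config$psf_sigma_um["z"]`, i.e. an axial focus scan of
#'   the instrument itself (the bead-profiling geometry); pass a small
#'   value (~2 um) to emulate a true confocal's fine optical sectioning.
#' @return rows x cols x n_slices numeric array with attributes
#'   `z_positions_um` and `pixel_size_um`.
#' @export
render_reference_stack <- function(phantom, config, z_positions_um,
                                   tile_origin_um = c(0, 0), fov_px = NULL,
                                   noise = FALSE, quantize = FALSE,
                                   seed = NULL, axial_sigma_um = NULL) {
  if (length(z_positions_um) == 0) abort("z_positions_um must be non-empty")
  if (is.unsorted(z_positions_um, strictly = TRUE)) {
    abort("z_positions_um must be strictly ascending")
  }
  fov_px <- if (is.null(fov_px)) config$fov_px else as.integer(fov_px)
  sz <- axial_sigma_um %||% unname(config$psf_sigma_um["z"])
  slices <- lapply(z_positions_um, function(zs) {
    dye_imgs <- accumulate_emission(
      phantom, config, tile_origin_um, fov_px, face_z_um = 0,
      depth_fun = function(rho2, R, zc) chord_gauss(rho2, R, zc, zs, sz),
      max_depth_um = max(z_positions_um) + 5 * sz
    )
    Reduce(`+`, dye_imgs) * config$gain
  })
  st <- array(unlist(slices), dim = c(fov_px[2], fov_px[1],
                                      length(z_positions_um)))
  st <- apply_noise_and_quantize(st, config, noise, quantize, seed)
  structure(st, z_positions_um = as.numeric(z_positions_um),
            pixel_size_um = config$pixel_size_um)
}
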