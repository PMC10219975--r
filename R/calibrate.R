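# Instrument calibration: bead-based PSF profiling and Beer-Lambert 1/e
# optical-sectioning-thickness estimation.

stack_spacing <- function(stack) {
  z <- attr(stack, "z_positions_um")
  if (is.null(z)) abort("stack lacks z_positions_um attribute")
  list(z = z, dz = if (length(z) > 1) median(diff(z)) else 1,
       pix = attr(stack, "pixel_size_um") %||% 1)
}

# 26-neighbourhood local maxima of a 3D array, as an index matrix.
# Plateau ties (a bead centred on a pixel boundary) keep exactly one
# representative: the comparison is >= towards lexicographically earlier
# neighbours and > towards later ones.
local_maxima_3d <- function(a, threshold) {
  d <- dim(a)
  is_max <- a > threshold
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    shifted <- array(-Inf, d)
    ys <- seq_len(d[1]); xs <- seq_len(d[2]); zs <- seq_len(d[3])
    ys_src <- ys + sy; xs_src <- xs + sx; zs_src <- zs + sz
    oky <- ys_src >= 1 & ys_src <= d[1]
    okx <- xs_src >= 1 & xs_src <= d[2]
    okz <- zs_src >= 1 & zs_src <= d[3]
    shifted[ys[oky], xs[okx], zs[okz]] <-
      a[ys_src[oky], xs_src[okx], zs_src[okz]]
    earlier <- sz < 0 || (sz == 0 && (sx < 0 || (sx == 0 && sy < 0)))
    is_max <- is_max & (if (earlier) a >= shifted else a > shifted)
  }
  which(is_max, arr.ind = TRUE)
}

#' Detect bead centroids in a 3D stack
#'
#' Finds strict local maxima above an adaptive threshold, suppresses
#' maxima closer than `min_separation_um` (keeping the brighter one, with
#' a warning that beads were merged), and refines each detection to a
#' subvoxel centroid by background-subtracted intensity weighting in a
#' local window.
#'
#' @param stack rows x cols x slices array with `z_positions_um` and
#'   `pixel_size_um` attributes (see [render_reference_stack()]).
#' @param min_separation_um minimum centre-to-centre distance.
#' @param threshold intensity threshold; default background median plus
#'   25% of the background-to-peak span.
#' @return Tibble (`x`, `y`, `z` in um, `peak`), brightest first.
#' @export
detect_beads <- function(stack, min_separation_um, threshold = NULL) {
  if (length(dim(stack)) != 3L || dim(stack)[3] < 3) {
    abort("stack must have at least 3 slices")
  }
  sp <- stack_spacing(stack)
  # light lateral smoothing stabilises maxima detection under noise;
  # centroid refinement below still uses the raw stack
  sm <- unclass(stack)
  for (k in seq_len(dim(sm)[3])) sm[, , k] <- smooth2d(sm[, , k], 1)
  bg <- median(sm)
  if (is.null(threshold)) threshold <- bg + 0.25 * (max(sm) - bg)
  if (max(sm) <= bg || threshold >= max(sm)) {
    abort("no beads detected: stack has no signal above background")
  }
  idx <- local_maxima_3d(sm, threshold)
  if (nrow(idx) == 0) abort("no beads detected above threshold")
  vals <- sm[idx]
  ord <- order(-vals)
  idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
  # positions in um (pixel centres; slices at their stated depths)
  pos <- cbind(x = (idx[, 2] - 0.5) * sp$pix,
               y = (idx[, 1] - 0.5) * sp$pix,
               z = sp$z[idx[, 3]])
  keep <- logical(nrow(pos))
  merged <- 0L
  for (i in seq_len(nrow(pos))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dists <- sqrt(colSums((t(pos[keep, , drop = FALSE]) - pos[i, ])^2))
    if (all(dists >= min_separation_um)) keep[i] <- TRUE else merged <- merged + 1L
  }
  if (merged > 0) {
    warn(sprintf("%d local maxima within min_separation merged into nearer detections",
                 merged))
  }
  idx <- idx[keep, , drop = FALSE]; vals <- vals[keep]
  # subvoxel refinement by intensity-weighted centroid
  d <- dim(stack)
  refine <- function(k) {
    c0 <- idx[k, ]
    ry <- max(1, c0[1] - 3):min(d[1], c0[1] + 3)
    rx <- max(1, c0[2] - 3):min(d[2], c0[2] + 3)
    rz <- max(1, c0[3] - 2):min(d[3], c0[3] + 2)
    w <- pmax(stack[ry, rx, rz, drop = FALSE] - bg, 0)
    sw <- sum(w)
    if (sw <= 0) {
      return(c((c0[2] - 0.5) * sp$pix, (c0[1] - 0.5) * sp$pix, sp$z[c0[3]]))
    }
    wy <- apply(w, 1, sum); wx <- apply(w, 2, sum); wz <- apply(w, 3, sum)
    c(sum(((rx - 0.5) * sp$pix) * wx) / sw,
      sum(((ry - 0.5) * sp$pix) * wy) / sw,
      sum(sp$z[rz] * wz) / sw)
  }
  ref <- t(vapply(seq_len(nrow(idx)), refine, numeric(3)))
  tibble::tibble(x = ref[, 1], y = ref[, 2], z = ref[, 3], peak = vals)
}

# Least-squares Gaussian + offset fit of a 1D profile.
fit_gaussian_1d <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  off0 <- min(y); a0 <- max(y) - off0
  w <- pmax(y - off0, 0)
  mu0 <- if (sum(w) > 0) sum(t * w) / sum(w) else mean(t)
  s0 <- if (sum(w) > 0) sqrt(sum((t - mu0)^2 * w) / sum(w)) else diff(range(t)) / 4
  s0 <- max(s0, diff(range(t)) / length(t) / 2)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-(t - mu)^2 / (2 * s^2)) + c0,
        start = start,
        lower = c(0, min(t), 1e-6, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fit <- try_fit(list(A = a0, mu = mu0, s = s0, c0 = off0))
  if (is.null(fit)) {
    # an exactly-optimal start can present a singular gradient; nudge it
    fit <- try_fit(list(A = 1.2 * a0 + 1e-6, mu = mu0 + s0 / 10,
                        s = 1.3 * s0, c0 = off0 - 0.01 * a0))
  }
  if (is.null(fit)) {
    # near-singular profiles (e.g. a single bright pixel) defeat the
    # nonlinear fit; fall back to weighted-moment estimates
    s_m <- max(s0, 1e-6)
    pred <- a0 * exp(-(t - mu0)^2 / (2 * s_m^2)) + off0
    return(list(amplitude = a0, center = mu0, sigma = s_m, offset = off0,
                fwhm = FWHM_PER_SIGMA * s_m,
                residual_rms = sqrt(mean((y - pred)^2))))
  }
  cf <- coef(fit)
  list(amplitude = unname(cf["A"]), center = unname(cf["mu"]),
       sigma = unname(cf["s"]), offset = unname(cf["c0"]),
       fwhm = FWHM_PER_SIGMA * unname(cf["s"]),
       residual_rms = sqrt(mean(stats::resid(fit)^2)))
}

# Interpolated 1D profile through a bead centroid along one axis.
axis_profile <- function(stack, centroid, axis, sp, half_width_um) {
  grid <- seq(-half_width_um, half_width_um, by = min(sp$pix, sp$dz))
  d <- dim(stack)
  jc <- min(max(1L, round(centroid["y"] / sp$pix + 0.5)), d[1])
  ic <- min(max(1L, round(centroid["x"] / sp$pix + 0.5)), d[2])
  kc <- which.min(abs(sp$z - centroid["z"]))
  if (axis == "x") {
    coords <- (seq_len(d[2]) - 0.5) * sp$pix - centroid["x"]
    vals <- stack[jc, , kc]
  } else if (axis == "y") {
    coords <- (seq_len(d[1]) - 0.5) * sp$pix - centroid["y"]
    vals <- stack[, ic, kc]
  } else {
    coords <- sp$z - centroid["z"]
    vals <- stack[jc, ic, ]
  }
  stats::approx(coords, vals, xout = grid, rule = 1)$y
}

#' Profile the PSF from detected beads
#'
#' Extracts 1D intensity profiles through each bead centroid along x, y
#' and z, aligns them on the centroid, averages across beads, and fits a
#' Gaussian plus offset per axis. FWHM is reported as
#' `2 * sqrt(2 * log(2)) * sigma` (~2.35482 sigma). Beads whose profile
#' cannot be extracted are excluded; a fitted sigma below the sampling
#' step triggers an under-sampling warning.
#'
#' @param stack bead image stack (as for [detect_beads()]).
#' @param centroids tibble from [detect_beads()] (`x`, `y`, `z` in um).
#' @param half_width_um profile half-length per side; default 4 lateral /
#'   axial sampling-scaled spans.
#' @return A `psf_profile`: tibble with one row per axis (`axis`,
#'   `amplitude`, `center_um`, `sigma_um`, `fwhm_um`, `offset`,
#'   `residual_rms`, `n_beads`).
#' @export
profile_psf <- function(stack, centroids, half_width_um = NULL) {
  if (nrow(centroids) < 1) abort("at least one bead centroid required")
  sp <- stack_spacing(stack)
  if (is.null(half_width_um)) {
    half_width_um <- c(x = 12 * sp$pix, y = 12 * sp$pix,
                       z = max(sp$z) - min(sp$z))
  } else if (length(half_width_um) == 1) {
    half_width_um <- c(x = half_width_um, y = half_width_um,
                       z = half_width_um)
  }
  rows <- purrr::map_dfr(c("x", "y", "z"), function(ax) {
    profs <- purrr::map(seq_len(nrow(centroids)), function(k) {
      axis_profile(stack, unlist(centroids[k, c("x", "y", "z")]), ax, sp,
                   half_width_um[[ax]])
    })
    profs <- purrr::keep(profs, ~ sum(is.finite(.x)) > 5)
    if (length(profs) == 0) abort(sprintf("no usable %s profiles", ax))
    avg <- colMeans(do.call(rbind, profs), na.rm = TRUE)
    grid <- seq(-half_width_um[[ax]], half_width_um[[ax]],
                by = min(sp$pix, sp$dz))
    fit <- fit_gaussian_1d(grid, avg)
    if (is.null(fit)) abort(sprintf("Gaussian fit failed on the %s profile", ax))
    step <- if (ax == "z") sp$dz else sp$pix
    if (fit$sigma < step) {
      warn(sprintf("%s profile under-sampled: sigma below the sampling step", ax))
    }
    tibble::tibble(axis = ax, amplitude = fit$amplitude,
                   center_um = fit$center, sigma_um = fit$sigma,
                   fwhm_um = fit$fwhm, offset = fit$offset,
                   residual_rms = fit$residual_rms,
                   n_beads = length(profs))
  })
  class(rows) <- c("psf_profile", class(rows))
  rows
}

#' Measure per-cell intensities on a block-face image
#'
#' Median intensity within a disk at each cell's known centroid, minus the
#' image background (median over the whole frame). This is the robust
#' per-cell statistic feeding the sectioning-thickness fit.
#'
#' @param image single-channel matrix or RGB array (channel `"R"` used).
#' @param cells tibble with `x`, `y` in um (and optionally `cell_id`).
#' @param radius_um disk radius; default 2.5 um.
#' @param channel channel used for RGB input.
#' @return Tibble (`cell_id`, `intensity`).
#' @export
measure_cell_intensities <- function(image, cells, radius_um = 2.5,
                                     channel = "R") {
  m <- to_gray(image, channel)
  pix <- attr(image, "pixel_size_um") %||% abort("image lacks pixel_size_um")
  bg <- median(m)
  rpx <- max(1L, ceiling(radius_um / pix))
  H <- nrow(m); W <- ncol(m)
  ids <- if ("cell_id" %in% names(cells)) cells$cell_id else seq_len(nrow(cells))
  vals <- vapply(seq_len(nrow(cells)), function(k) {
    ic <- round(cells$x[k] / pix + 0.5); jc <- round(cells$y[k] / pix + 0.5)
    rx <- max(1, ic - rpx):min(W, ic + rpx)
    ry <- max(1, jc - rpx):min(H, jc + rpx)
    rho2 <- outer(((ry - 0.5) * pix - cells$y[k])^2,
                  ((rx - 0.5) * pix - cells$x[k])^2, `+`)
    sel <- rho2 <= radius_um^2
    if (!any(sel)) return(NA_real_)
    median(m[ry, rx][sel]) - bg
  }, numeric(1))
  tibble::tibble(cell_id = ids, intensity = vals)
}

#' Estimate the optical sectioning thickness (1/e depth)
#'
#' Models the depth attenuation of per-cell intensity by Beer's law,
#' I(z) = I0 exp(-z/d): cells are binned by depth (default 2 um bins, the
#' conventional reference-stack spacing), bin medians are taken — the
#' averaging over many cells that tames the intensity heterogeneity
#' across and within cells — and ln(median) is regressed on depth by
#' least squares. The 1/e depth is -1/slope; a non-negative slope sets the
#' failure flag.
#'
#' @param cell_table tibble with `depth_um` and `intensity` per cell.
#' @param bin_width_um depth bin width (default 2).
#' @param min_cells minimum cells required (default 30).
#' @param nonlinear also refine by nonlinear least squares on the bin
#'   medians (exponential model)? The log-linear fit is the default
#'   estimator.
#' @return An `attenuation_fit`: list with `I0`, `d_hat_um`, `r_squared`,
#'   `n_cells`, `bins` tibble (`depth_um`, `median_intensity`, `n`),
#'   `failed`, and `d_hat_nls_um` when `nonlinear = TRUE`.
#' @export
estimate_sectioning_thickness <- function(cell_table, bin_width_um = 2,
                                          min_cells = 30,
                                          nonlinear = FALSE) {
  ct <- dplyr::filter(cell_table, is.finite(.data$depth_um),
                      is.finite(.data$intensity), .data$intensity > 0,
                      .data$depth_um >= 0)
  if (nrow(ct) < min_cells) {
    abort(sprintf("need at least %d cells with positive intensity", min_cells))
  }
  # bin depth = median cell depth in the bin (not the bin centre): the
  # median is a monotone statistic, so on exact exponential data the
  # (median depth, median intensity) points lie exactly on the decay line
  bins <- ct |>
    dplyr::mutate(bin = floor(.data$depth_um / bin_width_um)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(bin_center_um = (.data$bin[1] + 0.5) * bin_width_um,
                     depth_um = median(.data$depth_um),
                     median_intensity = median(.data$intensity),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$median_intensity > 0) |>
    dplyr::arrange(.data$depth_um)
  if (nrow(bins) < 3) abort("fewer than 3 usable depth bins")
  fit <- lm(log(median_intensity) ~ depth_um, data = bins)
  slope <- coef(fit)[["depth_um"]]
  failed <- slope >= 0
  lg <- log(bins$median_intensity)
  sst <- sum((lg - mean(lg))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 0
  out <- list(
    I0 = exp(coef(fit)[["(Intercept)"]]),
    d_hat_um = if (failed) NA_real_ else -1 / slope,
    r_squared = r2,
    n_cells = nrow(ct),
    bins = bins,
    bin_width_um = bin_width_um,
    failed = failed
  )
  if (nonlinear && !failed) {
    nfit <- tryCatch(
      minpack.lm::nlsLM(median_intensity ~ I0 * exp(-depth_um / d),
                        data = bins,
                        start = list(I0 = out$I0, d = out$d_hat_um)),
      error = function(e) NULL)
    out$d_hat_nls_um <- if (is.null(nfit)) NA_real_ else coef(nfit)[["d"]]
  }
  structure(out, class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  if (x$failed) {
    cat("<attenuation_fit> FAILED: intensity does not decay with depth\n")
  } else {
    cat(sprintf(
      "<attenuation_fit> 1/e depth = %.2f um (R^2 = %.3f, %d cells, %d bins)\n",
      x$d_hat_um, x$r_squared, x$n_cells, nrow(x$bins)))
  }
  invisible(x)
}

#' Assign per-cell depths from a reference z-stack
#'
#' For each segmented cell, the depth is the stack slice maximising the
#' mean intensity over the cell mask. Cells whose peak does not rise above
#' the stack background are excluded (depth NA).
#'
#' @param label_map integer label matrix from segmentation (0 background).
#' @param reference_stack co-registered stack (same pixel grid) from
#'   [render_reference_stack()].
#' @return Tibble (`label`, `depth_um`, `peak_mean`, `excluded`).
#' @export
assign_cell_depths <- function(label_map, reference_stack) {
  if (!all(dim(label_map) == dim(reference_stack)[1:2])) {
    abort("label map and stack pixel grids differ")
  }
  z <- attr(reference_stack, "z_positions_um") %||%
    abort("stack lacks z_positions_um")
  labs <- sort(unique(as.integer(label_map[label_map > 0])))
  if (length(labs) == 0) {
    return(tibble::tibble(label = integer(), depth_um = numeric(),
                          peak_mean = numeric(), excluded = logical()))
  }
  bg <- median(reference_stack)
  noise <- mad(reference_stack)
  lab_vec <- as.integer(label_map)
  means <- vapply(seq_along(z), function(k) {
    sl <- as.numeric(reference_stack[, , k])
    as.numeric(tapply(sl, factor(lab_vec, levels = c(0, labs)), mean))[-1]
  }, numeric(length(labs)))
  means <- matrix(means, nrow = length(labs))
  best <- apply(means, 1, which.max)
  peak <- means[cbind(seq_along(labs), best)]
  excluded <- peak <= bg + 3 * noise + 1e-12
  tibble::tibble(
    label = labs,
    depth_um = ifelse(excluded, NA_real_, z[best]),
    peak_mean = peak,
    excluded = excluded
  )
}

#' Correlation between a block-face image and a reference stack by depth
#'
#' Pearson correlation of the surface-excitation image with each slice of
#' a co-registered confocal-like stack, over the union of the two images'
#' foreground masks. For a surface-confined modality the profile is
#' maximal at the shallow slices and falls off beyond the optical
#' sectioning thickness.
#'
#' @param surface_image block-face image (RGB uses `channel`).
#' @param reference_stack co-registered stack.
#' @param channel channel for RGB surface images.
#' @param foreground_quantile if non-NULL, restrict each comparison to
#'   the union of the two images' foreground masks (pixels above this
#'   quantile). The default (NULL) correlates whole frames: mask-based
#'   selection biases r against structureless slices, so the whole-frame
#'   statistic is the null-calibrated one.
#' @return A `depth_correlation` tibble (`depth_um`, `r`, `n_px`).
#' @export
correlation_vs_depth <- function(surface_image, reference_stack,
                                 channel = "R",
                                 foreground_quantile = NULL) {
  s <- to_gray(surface_image, channel)
  if (!all(dim(s) == dim(reference_stack)[1:2])) {
    abort("surface image and stack pixel grids differ")
  }
  z <- attr(reference_stack, "z_positions_um") %||%
    abort("stack lacks z_positions_um")
  if (length(z) < 2) abort("stack needs at least 2 slices")
  fg_s <- if (is.null(foreground_quantile)) {
    matrix(TRUE, nrow(s), ncol(s))
  } else {
    s > quantile(s, foreground_quantile)
  }
  rows <- purrr::map_dfr(seq_along(z), function(k) {
    sl <- reference_stack[, , k]
    mask <- if (is.null(foreground_quantile)) fg_s else
      fg_s | (sl > quantile(sl, foreground_quantile))
    r <- if (sum(mask) < 3 || sd(sl[mask]) == 0 || sd(s[mask]) == 0) {
      NA_real_
    } else {
      stats::cor(as.numeric(s[mask]), as.numeric(sl[mask]))
    }
    tibble::tibble(depth_um = z[k], r = r, n_px = sum(mask))
  })
  rows <- dplyr::arrange(rows, .data$depth_um)
  class(rows) <- c("depth_correlation", class(rows))
  rows
}
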