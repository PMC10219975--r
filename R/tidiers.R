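# broom-style tidiers for fitted objects.

#' Tidy an attenuation fit
#'
#' @param x an `attenuation_fit`.
#' @param ... unused.
#' @return The depth-bin table with the fitted exponential
#'   (`depth_um`, `median_intensity`, `n`, `fitted`).
#' @export
tidy.attenuation_fit <- function(x, ...) {
  dplyr::mutate(x$bins, fitted = if (x$failed) NA_real_ else
    x$I0 * exp(-.data$depth_um / x$d_hat_um))
}

#' One-row summary of an attenuation fit
#'
#' @param x an `attenuation_fit`.
#' @param ... unused.
#' @return Tibble (`I0`, `d_hat_um`, `r_squared`, `n_cells`, `n_bins`,
#'   `failed`).
#' @export
glance.attenuation_fit <- function(x, ...) {
  tibble::tibble(I0 = x$I0, d_hat_um = x$d_hat_um,
                 r_squared = x$r_squared, n_cells = x$n_cells,
                 n_bins = nrow(x$bins), failed = x$failed)
}

#' One-row summary of a PSF profile
#'
#' @param x a `psf_profile`.
#' @param ... unused.
#' @return Tibble with `fwhm_x_um`, `fwhm_y_um`, `fwhm_z_um`, `n_beads`.
#' @export
glance.psf_profile <- function(x, ...) {
  wide <- setNames(x$fwhm_um, paste0("fwhm_", x$axis, "_um"))
  tibble::tibble(!!!as.list(wide), n_beads = max(x$n_beads))
}

#' Tidy a multi-group statistics report
#'
#' @param x a `stat_report`.
#' @param ... unused.
#' @return Long tibble with one row per test (Welch ANOVA, each Tukey
#'   pair, Shapiro-Wilk).
#' @export
tidy.stat_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(method = "welch_anova", term = "group",
                   statistic = x$welch$F, df1 = x$welch$df1,
                   df2 = x$welch$df2, p_value = x$welch$p_value),
    tibble::tibble(method = "tukey_hsd", term = x$tukey$pair,
                   statistic = x$tukey$diff, df1 = NA_real_,
                   df2 = NA_real_, p_value = x$tukey$p_adj),
    tibble::tibble(method = "shapiro_wilk", term = "pooled",
                   statistic = x$shapiro$W, df1 = NA_real_,
                   df2 = NA_real_, p_value = x$shapiro$p_value)
  )
}

#' One-row summary of a multi-group statistics report
#'
#' @param x a `stat_report`.
#' @param ... unused.
#' @return The Welch ANOVA row plus the Shapiro-Wilk W and flag.
#' @export
glance.stat_report <- function(x, ...) {
  tibble::tibble(F = x$welch$F, df1 = x$welch$df1, df2 = x$welch$df2,
                 p_value = x$welch$p_value, shapiro_w = x$shapiro$W,
                 flagged = x$flagged)
}

#' Tidy a tile plan
#'
#' @param x a `tile_plan`.
#' @param ... unused.
#' @return The tile origin table.
#' @export
tidy.tile_plan <- function(x, ...) x$tiles

#' One-row summary of a tile plan
#'
#' @param x a `tile_plan`.
#' @param ... unused.
#' @return Tibble (`n_x`, `n_y`, `n_tiles`, `overlap_fraction`,
#'   `fov_x_mm`, `fov_y_mm`).
#' @export
glance.tile_plan <- function(x, ...) {
  tibble::tibble(n_x = x$n_x, n_y = x$n_y, n_tiles = nrow(x$tiles),
                 overlap_fraction = x$overlap_fraction,
                 fov_x_mm = x$fov_mm[1], fov_y_mm = x$fov_mm[2])
}

#' Tidy a tissue phantom
#'
#' @param x a `tissue_phantom`.
#' @param ... unused.
#' @return The ground-truth cell table.
#' @export
tidy.tissue_phantom <- function(x, ...) x$cells

#' One-row-per-region summary of a tissue phantom
#'
#' @param x a `tissue_phantom`.
#' @param ... unused.
#' @return Tibble with nominal density, realised count and realised
#'   density per region.
#' @export
glance.tissue_phantom <- function(x, ...) {
  vols <- region_volume_mm3(x$regions)
  counts <- table(factor(x$cells$region_id, levels = x$regions$region_id))
  tibble::tibble(
    region_id = x$regions$region_id, name = x$regions$name,
    volume_mm3 = vols,
    nominal_density_per_mm3 = x$regions$density_per_mm3,
    n_cells = as.integer(counts),
    realised_density_per_mm3 = as.integer(counts) / vols
  )
}
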