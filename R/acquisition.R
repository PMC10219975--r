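#' Stage step resolution
#'
#' Linear resolution of a micrometer-driven stage axis: one motor step of
#' `step_angle_deg` on a screw of `pitch_um_per_rev` advances
#' `pitch * step_angle / 360` micrometres. The conventional stepper
#' (0.9 degrees) on a 500 um/rev micrometer gives 1.25 um.
#'
#' @param step_angle_deg motor step angle in degrees.
#' @param pitch_um_per_rev screw pitch in um per revolution.
#' @return Resolution in um per step.
#' @export
stage_resolution <- function(step_angle_deg = 0.9, pitch_um_per_rev = 500) {
  if (step_angle_deg <= 0 || pitch_um_per_rev <= 0) {
    abort("step angle and pitch must be positive")
  }
  pitch_um_per_rev * step_angle_deg / 360
}

#' Quantise a commanded move to whole motor steps
#'
#' @param distance_um commanded move (um, may be negative).
#' @param resolution_um um per step (> 0).
#' @param travel_limit_um optional axis travel limit; moves beyond it error.
#' @return List `steps` (integer, round-half-even) and `residual_um`
#'   (`distance - steps * resolution`, at most half a step).
#' @export
distance_to_steps <- function(distance_um, resolution_um,
                              travel_limit_um = NULL) {
  if (resolution_um <= 0) abort("resolution must be positive")
  if (!is.null(travel_limit_um) && abs(distance_um) > travel_limit_um) {
    abort("commanded move exceeds axis travel limit")
  }
  steps <- round(distance_um / resolution_um) # IEC 60559 half-even
  list(steps = as.integer(steps),
       residual_um = distance_um - steps * resolution_um)
}

#' Stage geometry configuration
#'
#' @param step_angle_deg stepper step angle (default 0.9).
#' @param pitch_um_per_rev micrometer pitch (default 500 um/rev).
#' @param travel_mm named axis travel limits in mm.
#' @return A `stage_config` list including the derived `resolution_um`.
#' @export
stage_config <- function(step_angle_deg = 0.9, pitch_um_per_rev = 500,
                         travel_mm = c(x = 25, y = 50, z = 25)) {
  stopifnot(all(travel_mm > 0))
  structure(list(
    step_angle_deg = step_angle_deg,
    pitch_um_per_rev = pitch_um_per_rev,
    travel_mm = travel_mm,
    resolution_um = stage_resolution(step_angle_deg, pitch_um_per_rev)
  ), class = "stage_config")
}

#' Plan a tile grid with overlap
#'
#' Computes the tile origins needed to cover a lateral extent with a fixed
#' field of view and fractional overlap. Stride is `fov * (1 - overlap)`;
#' per axis the count is 1 when the extent fits in one field, otherwise
#' `ceil((extent - fov) / stride) + 1`, with the last tile shifted back so
#' it ends exactly at the extent (tiles never leave the tissue). Tiles are
#' visited in serpentine (boustrophedon) order.
#'
#' @param extent_mm lateral extents (x, y) to cover, in mm.
#' @param fov_mm field of view (x, y) in mm (default 1.3 x 1.0).
#' @param overlap_fraction fractional overlap between adjacent tiles in
#'   \[0, 0.9\] (default 0.20), applied to both axes.
#' @return A `tile_plan`: list with the grid dimensions and a `tiles`
#'   tibble (`tile_id`, `row`, `col`, `x_mm`, `y_mm`, `visit_order`).
#' @export
plan_tiles <- function(extent_mm, fov_mm = c(1.3, 1.0),
                       overlap_fraction = 0.20) {
  stopifnot(length(extent_mm) == 2, length(fov_mm) == 2)
  if (any(fov_mm <= 0) || any(extent_mm <= 0)) {
    abort("extent and fov must be positive")
  }
  if (overlap_fraction < 0 || overlap_fraction > 0.9) {
    abort("overlap_fraction must lie in [0, 0.9]")
  }
  stride <- fov_mm * (1 - overlap_fraction)
  axis_origins <- function(extent, fov, stride) {
    if (extent <= fov) return(0)
    n <- ceiling((extent - fov) / stride) + 1
    o <- (seq_len(n) - 1) * stride
    o[n] <- extent - fov # shift-to-fit: last tile ends at the extent
    o
  }
  ox <- axis_origins(extent_mm[1], fov_mm[1], stride[1])
  oy <- axis_origins(extent_mm[2], fov_mm[2], stride[2])
  grid <- tidyr::expand_grid(row = seq_along(oy), col = seq_along(ox))
  grid <- dplyr::mutate(grid,
    x_mm = ox[.data$col], y_mm = oy[.data$row],
    serp_col = ifelse(.data$row %% 2 == 1, .data$col,
                      length(ox) + 1 - .data$col))
  grid <- dplyr::arrange(grid, .data$row, .data$serp_col)
  grid <- dplyr::mutate(grid, visit_order = dplyr::row_number(),
                        tile_id = dplyr::row_number())
  structure(list(
    extent_mm = as.numeric(extent_mm), fov_mm = as.numeric(fov_mm),
    overlap_fraction = overlap_fraction,
    n_x = length(ox), n_y = length(oy),
    tiles = dplyr::select(grid, "tile_id", "row", "col", "x_mm", "y_mm",
                          "visit_order")
  ), class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf(
    "<tile_plan> %d x %d tiles (%d total), fov %g x %g mm, overlap %g%%\n",
    x$n_x, x$n_y, nrow(x$tiles), x$fov_mm[1], x$fov_mm[2],
    100 * x$overlap_fraction))
  invisible(x)
}

#' Plan a serial-section schedule
#'
#' Block faces sit at 0, t, 2t, ... with `n = floor(z_extent / thickness)`
#' faces. Sectioning thinner than the imaged depth would re-image material
#' seen at the previous face, so a thickness at or below the attenuation
#' depth triggers a warning when that depth is supplied.
#'
#' @param z_extent_um axial extent of the block in um.
#' @param thickness_um section thickness in um (conventionally 50 or 100).
#' @param attenuation_depth_um optional 1/e imaged depth used for the
#'   re-imaging warning.
#' @return A `section_schedule`: list with a `faces` tibble
#'   (`section_index`, `face_z_um`) and the parameters.
#' @export
schedule_sections <- function(z_extent_um, thickness_um,
                              attenuation_depth_um = NULL) {
  if (z_extent_um <= 0 || thickness_um <= 0) {
    abort("z extent and thickness must be positive")
  }
  if (thickness_um > z_extent_um) {
    warn("section thickness exceeds block extent: single face")
    n <- 1L
  } else {
    n <- as.integer(floor(z_extent_um / thickness_um))
  }
  if (!is.null(attenuation_depth_um) &&
      thickness_um <= attenuation_depth_um) {
    warn("section thickness <= attenuation depth: faces re-image previously imaged material")
  }
  structure(list(
    thickness_um = thickness_um, z_extent_um = z_extent_um,
    n_sections = n,
    faces = tibble::tibble(section_index = seq_len(n),
                           face_z_um = (seq_len(n) - 1) * thickness_um)
  ), class = "section_schedule")
}

#' Run a virtual serial block-face acquisition
#'
#' For every face in the schedule, renders every tile of the plan in
#' serpentine order and collects a manifest. Images are kept in memory
#' and optionally written as TIFF files.
#'
#' @param phantom a `tissue_phantom`.
#' @param config an [optical_config()].
#' @param tile_plan a [plan_tiles()] result.
#' @param schedule a [schedule_sections()] result.
#' @param seed root seed; each image draws noise from a substream derived
#'   from (seed, section, tile), so runs are reproducible.
#' @param noise add camera noise?
#' @param out_dir if non-NULL, write each image as `<out_dir>/s###_t###.tif`.
#' @return A `section_series`: list with `images` (named list of
#'   `blockface_image`), `manifest` tibble (`section_index`, `face_z_um`,
#'   `tile_id`, `row`, `col`, `x_mm`, `y_mm`, `visit_order`, `key`,
#'   `file`), the plan, the schedule and the config.
#' @export
run_virtual_acquisition <- function(phantom, config, tile_plan, schedule,
                                    seed = 1, noise = TRUE,
                                    out_dir = NULL) {
  if (schedule$z_extent_um > phantom$box_um[3]) {
    warn("phantom shallower than schedule: truncating sections")
    keep <- schedule$faces$face_z_um < phantom$box_um[3]
    schedule$faces <- schedule$faces[keep, ]
    schedule$n_sections <- sum(keep)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  images <- list()
  rows <- list()
  for (k in seq_len(nrow(schedule$faces))) {
    sec <- schedule$faces$section_index[k]
    fz <- schedule$faces$face_z_um[k]
    for (t in seq_len(nrow(tile_plan$tiles))) {
      tl <- tile_plan$tiles[t, ]
      key <- sprintf("s%03d_t%03d", sec, tl$tile_id)
      img <- render_block_face(
        phantom, config, face_z_um = fz,
        tile_origin_um = c(tl$x_mm, tl$y_mm) * 1000,
        noise = noise,
        seed = substream_seed(seed, key),
        section_index = sec
      )
      file <- NA_character_
      if (!is.null(out_dir)) {
        file <- file.path(out_dir, paste0(key, ".tif"))
        write_image_tiff(img, file)
      }
      images[[key]] <- img
      rows[[key]] <- tibble::tibble(
        section_index = sec, face_z_um = fz, tile_id = tl$tile_id,
        row = tl$row, col = tl$col, x_mm = tl$x_mm, y_mm = tl$y_mm,
        visit_order = tl$visit_order, key = key, file = file
      )
    }
  }
  structure(list(
    images = images, manifest = dplyr::bind_rows(rows),
    tile_plan = tile_plan, schedule = schedule, config = config
  ), class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("<section_series> %d sections x %d tiles = %d images\n",
              x$schedule$n_sections, nrow(x$tile_plan$tiles),
              length(x$images)))
  invisible(x)
}
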