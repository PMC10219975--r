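# Experiment configuration (YAML) and the end-to-end pipeline.

config_known_keys <- list(
  top = c("seed", "phantom", "optics", "stage", "tiles", "sections",
          "preprocess", "segmentation", "quantify"),
  phantom = c("box_um", "regions", "sigma_log", "nucleus_radius_um",
              "soma_radius_um"),
  region = c("region_id", "name", "xlim", "ylim", "zlim",
             "density_per_mm3", "dye_means"),
  optics = c("attenuation_depth_um", "psf_sigma_um", "pixel_size_um",
             "fov_mm", "gain", "bit_depth", "exposure_ms", "power_mW",
             "illumination", "noise"),
  stage = c("step_angle_deg", "pitch_um_per_rev", "travel_mm"),
  tiles = c("overlap_fraction"),
  sections = c("thickness_um"),
  preprocess = c("flat_field", "color_correct", "to_16bit"),
  segmentation = c("min_area_um2", "max_area_um2", "smooth_sigma_um",
                   "watershed_tolerance"),
  quantify = c("channel", "compare_regions")
)

config_defaults <- list(
  optics = list(attenuation_depth_um = 20, pixel_size_um = 2,
                fov_mm = c(1.3, 1.0), gain = 25, bit_depth = 8L,
                exposure_ms = 30, power_mW = 8.13,
                psf_sigma_um = c(x = 1.5, y = 1.53, z = 13.8)),
  stage = list(step_angle_deg = 0.9, pitch_um_per_rev = 500,
               travel_mm = c(x = 25, y = 50, z = 25)),
  tiles = list(overlap_fraction = 0.20),
  sections = list(thickness_um = 50),
  preprocess = list(flat_field = TRUE, color_correct = FALSE,
                    to_16bit = FALSE),
  segmentation = list(min_area_um2 = 15, max_area_um2 = 400,
                      smooth_sigma_um = 1.5, watershed_tolerance = 0.05),
  quantify = list(channel = "R", compare_regions = NULL),
  phantom = list(sigma_log = 0.3, nucleus_radius_um = 3,
                 soma_radius_um = 5)
)

reject_unknown <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    abort(sprintf("unknown key(s) in %s: %s", where,
                  paste(extra, collapse = ", ")))
  }
}

#' Validate and normalise an experiment configuration
#'
#' Rejects unknown keys, checks bounds, injects defaults and records
#' which defaults were injected (`attr(config, "injected_defaults")`).
#' A seed is mandatory: every stochastic stage of the pipeline draws from
#' a substream of it.
#'
#' @param config named list (typically from YAML).
#' @return An `experiment_config`.
#' @export
validate_config <- function(config) {
  reject_unknown(config, config_known_keys$top, "config")
  if (is.null(config$seed)) abort("missing required key: seed")
  if (is.null(config$phantom)) abort("missing required key: phantom")
  reject_unknown(config$phantom, config_known_keys$phantom, "phantom")
  if (is.null(config$phantom$box_um)) {
    abort("missing required key: phantom$box_um")
  }
  if (is.null(config$phantom$regions) ||
      length(config$phantom$regions) == 0) {
    abort("missing required key: phantom$regions")
  }
  for (r in config$phantom$regions) {
    reject_unknown(r, config_known_keys$region, "phantom$regions[]")
    for (key in c("region_id", "xlim", "ylim", "zlim", "density_per_mm3")) {
      if (is.null(r[[key]])) {
        abort(sprintf("missing required key: phantom$regions[]$%s", key))
      }
    }
  }
  injected <- character()
  for (sec in names(config_defaults)) {
    block <- config[[sec]] %||% list()
    if (sec %in% names(config_known_keys)) {
      reject_unknown(block, config_known_keys[[sec]], sec)
    }
    for (key in names(config_defaults[[sec]])) {
      if (is.null(block[[key]])) {
        block[[key]] <- config_defaults[[sec]][[key]]
        injected <- c(injected, paste(sec, key, sep = "$"))
      }
    }
    config[[sec]] <- block
  }
  # normalise vector-valued fields (YAML sequences come back as lists and
  # drop names) so configs compare equal across save/load round trips
  config$phantom$box_um <- unname(unlist(config$phantom$box_um))
  config$optics$fov_mm <- unname(unlist(config$optics$fov_mm))
  s <- unname(unlist(config$optics$psf_sigma_um))
  config$optics$psf_sigma_um <- setNames(s, c("x", "y", "z"))
  tv <- unname(unlist(config$stage$travel_mm))
  config$stage$travel_mm <- setNames(tv, c("x", "y", "z"))
  if (!is.null(config$quantify$compare_regions)) {
    config$quantify$compare_regions <-
      unname(unlist(config$quantify$compare_regions))
  }
  config$seed <- as.integer(config$seed)
  ov <- config$tiles$overlap_fraction
  if (ov < 0 || ov > 0.9) abort("tiles$overlap_fraction must lie in [0, 0.9]")
  if (config$sections$thickness_um <= 0) abort("sections$thickness_um must be positive")
  if (any(unlist(config$phantom$box_um) <= 0)) abort("phantom$box_um must be positive")
  structure(config, injected_defaults = injected,
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' @param path YAML file describing an imaging session.
#' @return A validated `experiment_config` with defaults injected.
#' @export
load_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Save an experiment configuration to YAML
#'
#' load-save-load is stable: the saved file reloads to an equal config.
#'
#' @param config an `experiment_config` (or compatible list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

phantom_from_config <- function(config) {
  ph <- config$phantom
  regions <- purrr::map_dfr(ph$regions, function(r) {
    dm <- r$dye_means %||% list(hoechst = 1, pi = 1, af594 = 0)
    region_model(r$region_id, r$name %||% paste0("region_", r$region_id),
                 unlist(r$xlim), unlist(r$ylim), unlist(r$zlim),
                 r$density_per_mm3, unlist(dm))
  })
  generate_tissue_phantom(
    unlist(ph$box_um), regions,
    seed = substream_seed(config$seed, "phantom"),
    sigma_log = ph$sigma_log,
    nucleus_radius_um = ph$nucleus_radius_um,
    soma_radius_um = ph$soma_radius_um
  )
}

optics_from_config <- function(config) {
  oc <- config$optics
  optical_config(
    attenuation_depth_um = oc$attenuation_depth_um,
    psf_sigma_um = {
      s <- unlist(oc$psf_sigma_um)
      if (is.null(names(s))) names(s) <- c("x", "y", "z")
      s
    },
    pixel_size_um = oc$pixel_size_um,
    fov_mm = unlist(oc$fov_mm),
    gain = oc$gain, bit_depth = oc$bit_depth,
    exposure_ms = oc$exposure_ms, power_mW = oc$power_mW
  )
}

pipeline_log <- function(lines, file) {
  cat(paste0(lines, "\n"), file = file, append = TRUE, sep = "")
}

#' Run the end-to-end virtual experiment
#'
#' Phantom generation, tile/section planning, virtual acquisition,
#' preprocessing, stitching, segmentation, regional quantification and
#' statistics, writing every artifact into a run directory: tile and
#' mosaic TIFFs, `manifest.csv`, `cells.csv`, `counts.csv`,
#' `sunburst.csv`, `stats.yaml` and `run.log`. Deterministic given the
#' config seed.
#'
#' @param config an `experiment_config` (see [load_config()]).
#' @param out_dir run directory (created if needed).
#' @param write_images write per-tile and mosaic TIFFs (default mosaics
#'   only)?
#' @return Invisibly, a list with the phantom, series, mosaics, cell
#'   table, `region_counts`, sunburst table, stats and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         write_images = c("mosaics", "all", "none")) {
  write_images <- match.arg(write_images)
  config <- validate_config(unclass(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  cat("", file = log_file)
  pipeline_log(c(
    sprintf("duvtomo %s | R %s", as.character(utils::packageVersion("duvtomo")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("injected defaults: %s",
            paste(attr(config, "injected_defaults"), collapse = ", "))
  ), log_file)
  stage <- "phantom"
  result <- tryCatch({
    phantom <- phantom_from_config(config)
    pipeline_log(sprintf("phantom: %d cells, %d regions",
                         nrow(phantom$cells), nrow(phantom$regions)),
                 log_file)
    stage <- "planning"
    optics <- optics_from_config(config)
    plan <- plan_tiles(phantom$box_um[1:2] / 1000, optics$fov_mm,
                       config$tiles$overlap_fraction)
    schedule <- schedule_sections(phantom$box_um[3],
                                  config$sections$thickness_um)
    if (schedule$n_sections < 1) abort("schedule yields no sections")
    stage <- "acquisition"
    series <- run_virtual_acquisition(
      phantom, optics, plan, schedule,
      seed = substream_seed(config$seed, "acquire"),
      out_dir = if (write_images == "all") file.path(out_dir, "tiles"))
    stage <- "preprocess"
    ff <- NULL
    # the median-across-tiles field estimate needs many distinct stage
    # positions; medianing repeated views of one position would absorb
    # the anatomy into the "field". With few positions, fall back to a
    # reference-slide field: the virtual acquisition of a uniform
    # fluorescent target, i.e. the instrument's illumination field.
    if (isTRUE(config$preprocess$flat_field)) {
      if (nrow(plan$tiles) >= 10) {
        ff <- estimate_flat_field(series$images,
                                  channel = config$quantify$channel)
        pipeline_log("flat-field: estimated from tiles and applied", log_file)
      } else {
        fov_px <- dim(series$images[[1]])[1:2]
        fld <- illumination_field(fov_px[2], fov_px[1],
                                  optics$illumination)
        ff <- structure(list(field = fld / mean(fld), n_tiles = 0L),
                        class = "flat_field_model")
        pipeline_log("flat-field: reference-slide field applied (too few tile positions to estimate)",
                     log_file)
      }
      series$images <- lapply(series$images, flat_field_correct,
                              field = ff$field)
    } else {
      pipeline_log("flat-field: disabled", log_file)
    }
    if (isTRUE(config$preprocess$color_correct)) {
      M <- solve(optics$mixing_matrix[, 1:3])
      series$images <- lapply(series$images, color_correct, gains = M)
      pipeline_log("colour correction: unmixed with inverse mixing matrix",
                   log_file)
    }
    stage <- "stitch"
    n_tiles <- nrow(plan$tiles)
    mosaics <- lapply(schedule$faces$section_index, function(s) {
      stitch_section(series, s, refine = n_tiles > 1)
    })
    names(mosaics) <- sprintf("section_%03d", schedule$faces$section_index)
    if (write_images != "none") {
      mdir <- file.path(out_dir, "mosaics")
      dir.create(mdir, showWarnings = FALSE)
      for (nm in names(mosaics)) {
        img <- mosaics[[nm]]$mosaic
        if (isTRUE(config$preprocess$to_16bit)) img <- to_16bit(img)
        write_image_tiff(img, file.path(mdir, paste0(nm, ".tif")))
      }
    }
    stage <- "segmentation"
    seg_par <- config$segmentation
    cells <- purrr::map_dfr(seq_along(mosaics), function(i) {
      mo <- mosaics[[i]]
      seg <- segment_cells(
        mo$mosaic, pixel_size_um = optics$pixel_size_um,
        channel = config$quantify$channel,
        smooth_sigma_um = seg_par$smooth_sigma_um,
        min_area_um2 = seg_par$min_area_um2,
        max_area_um2 = seg_par$max_area_um2,
        watershed_tolerance = seg_par$watershed_tolerance,
        section_index = mo$section_index
      )
      seg$cells
    })
    pipeline_log(sprintf("segmentation: %d cells over %d sections",
                         nrow(cells), length(mosaics)), log_file)
    stage <- "quantification"
    label_img <- region_label_image(phantom, optics$pixel_size_um)
    region_names <- dplyr::select(phantom$regions, "region_id", "name")
    cells <- assign_regions(cells, label_img,
                            region_names = region_names)
    areas <- region_areas_from_labels(label_img)
    counts <- count_and_density(cells, areas)
    tree <- tibble::tibble(
      node = c("root", phantom$regions$name),
      parent = c(NA_character_, rep("root", nrow(phantom$regions)))
    )
    own <- cells |>
      dplyr::filter(.data$region_id > 0) |>
      dplyr::count(node = .data$region_name, name = "count")
    sunburst <- aggregate_region_tree(own, tree)
    stage <- "statistics"
    stats_out <- list()
    cmp <- config$quantify$compare_regions
    if (!is.null(cmp) && length(cmp) == 2) {
      wide <- counts |>
        dplyr::filter(.data$region_id %in% unlist(cmp)) |>
        dplyr::select("section_index", "region_id", "density_per_mm2") |>
        tidyr::pivot_wider(names_from = "region_id",
                           values_from = "density_per_mm2")
      a <- wide[[as.character(cmp[[1]])]]
      b <- wide[[as.character(cmp[[2]])]]
      stats_out$paired_t_density <- paired_t(a, b)
      cw <- counts |>
        dplyr::filter(.data$region_id %in% unlist(cmp)) |>
        dplyr::select("section_index", "region_id", "n_cells") |>
        tidyr::pivot_wider(names_from = "region_id",
                           values_from = "n_cells")
      stats_out$paired_t_count <- paired_t(
        cw[[as.character(cmp[[1]])]], cw[[as.character(cmp[[2]])]])
    }
    if (length(unique(cells$section_index)) >= 3 &&
        all(table(cells$section_index) >= 2)) {
      stats_out$intensity_by_section <- group_stats(
        cells$median_intensity, cells$section_index)
    }
    stage <- "write"
    write.csv(series$manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
    write.csv(as.data.frame(counts), file.path(out_dir, "counts.csv"),
              row.names = FALSE)
    write.csv(sunburst, file.path(out_dir, "sunburst.csv"),
              row.names = FALSE)
    yaml_stats <- lapply(stats_out, function(s) {
      if (inherits(s, "stat_report")) {
        list(welch = as.list(s$welch), shapiro = as.list(s$shapiro))
      } else {
        as.list(s)
      }
    })
    yaml::write_yaml(yaml_stats, file.path(out_dir, "stats.yaml"))
    save_config(config, file.path(out_dir, "config.yaml"))
    pipeline_log("pipeline complete", log_file)
    list(phantom = phantom, series = series, mosaics = mosaics,
         cells = cells, counts = counts, sunburst = sunburst,
         stats = stats_out, flat_field = ff, out_dir = out_dir)
  }, error = function(e) {
    pipeline_log(sprintf("FAILED at stage %s: %s", stage,
                         conditionMessage(e)), log_file)
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
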