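#' Describe a labelled tissue region
#'
#' A region is an axis-aligned sub-volume of the phantom bounding box with
#' a nominal cell density and a mean emission amplitude per dye. The
#' default dye set mirrors a nuclear stain (Hoechst-like), a nuclear +
#' perikaryal Nissl-like stain (propidium-iodide-like) and an
#' immunolabel (AF594-like).
#'
#' @param region_id positive integer label (0 is reserved for background).
#' @param name human-readable region name.
#' @param xlim,ylim,zlim numeric length-2 extents in micrometres.
#' @param density_per_mm3 nominal cell density (cells per cubic mm).
#' @param dye_means named numeric vector of mean emission amplitudes per
#'   dye (arbitrary units, >= 0).
#' @return A one-row tibble; rows from several calls can be bound together
#'   and passed to [generate_tissue_phantom()].
#' @export
region_model <- function(region_id, name, xlim, ylim, zlim,
                         density_per_mm3,
                         dye_means = c(hoechst = 1, pi = 1, af594 = 0)) {
  stopifnot(
    is_scalar_number(region_id), region_id >= 1,
    length(xlim) == 2, length(ylim) == 2, length(zlim) == 2,
    is_scalar_number(density_per_mm3), density_per_mm3 >= 0,
    all(dye_means >= 0), !is.null(names(dye_means))
  )
  tibble::tibble(
    region_id = as.integer(region_id), name = as.character(name),
    x0 = xlim[1], x1 = xlim[2], y0 = ylim[1], y1 = ylim[2],
    z0 = zlim[1], z1 = zlim[2],
    density_per_mm3 = density_per_mm3,
    dye_means = list(dye_means)
  )
}

region_volume_mm3 <- function(r) {
  (r$x1 - r$x0) * (r$y1 - r$y0) * (r$z1 - r$z0) / 1e9
}

check_regions <- function(regions, box_um) {
  vols <- region_volume_mm3(regions)
  if (any(vols <= 0)) abort("zero-volume region in region table")
  inside <- regions$x0 >= 0 & regions$x1 <= box_um[1] &
    regions$y0 >= 0 & regions$y1 <= box_um[2] &
    regions$z0 >= 0 & regions$z1 <= box_um[3]
  if (!all(inside)) abort("region extends outside the phantom bounding box")
  n <- nrow(regions)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ox <- min(regions$x1[c(i, j)]) - max(regions$x0[c(i, j)])
      oy <- min(regions$y1[c(i, j)]) - max(regions$y0[c(i, j)])
      oz <- min(regions$z1[c(i, j)]) - max(regions$z0[c(i, j)])
      if (ox > 0 && oy > 0 && oz > 0) {
        abort(sprintf("regions %d and %d overlap", regions$region_id[i],
                      regions$region_id[j]))
      }
    }
  }
  invisible(vols)
}

#' Generate a ground-truth tissue phantom
#'
#' Places cells uniformly at random inside each region, with per-region
#' Poisson counts (rate = density x region volume) and per-dye lognormal
#' amplitude jitter. Cells are dual-compartment: a nuclear sphere inside a
#' soma sphere whose shell carries the Nissl-like perikaryal signal.
#' Placement does not enforce non-overlap; touching cells occur, as in
#' tissue, and segmentation is expected to handle them.
#'
#' @param box_um numeric length-3 phantom extents (x, y, z) in micrometres;
#'   z = 0 is the first block face, increasing into the block.
#' @param regions tibble of regions from [region_model()] (rows bound
#'   together). Regions must be disjoint and inside the box.
#' @param seed integer seed; identical (arguments, seed) give a
#'   bit-identical phantom.
#' @param sigma_log lognormal jitter (sd of log amplitude) applied around
#'   each dye mean; the draw is mean-preserving.
#' @param nucleus_radius_um,soma_radius_um mean compartment radii; a mild
#'   lognormal size jitter (sd of log = 0.1) is applied, preserving
#'   soma >= nucleus.
#' @return A `tissue_phantom`: list with `box_um`, `regions`, `cells`
#'   tibble (`cell_id`, `x`, `y`, `z`, radii, one `amp_<dye>` column per
#'   dye, `region_id`), an empty `beads` tibble and the seed.
#' @export
generate_tissue_phantom <- function(box_um, regions, seed,
                                    sigma_log = 0.3,
                                    nucleus_radius_um = 3,
                                    soma_radius_um = 5) {
  stopifnot(length(box_um) == 3, all(box_um > 0),
            soma_radius_um >= nucleus_radius_um, nucleus_radius_um > 0)
  check_regions(regions, box_um)
  dyes <- names(regions$dye_means[[1]])
  cells <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      n <- rpois(1, r$density_per_mm3 * region_volume_mm3(r))
      if (n == 0) return(NULL)
      size_jit <- rlnorm(n, -0.1^2 / 2, 0.1)
      amps <- purrr::map(dyes, function(d) {
        r$dye_means[[1]][[d]] * rlnorm(n, -sigma_log^2 / 2, sigma_log)
      })
      names(amps) <- paste0("amp_", dyes)
      tibble::tibble(
        x = runif(n, r$x0, r$x1),
        y = runif(n, r$y0, r$y1),
        z = runif(n, r$z0, r$z1),
        nucleus_radius = nucleus_radius_um * size_jit,
        soma_radius = soma_radius_um * size_jit,
        !!!amps,
        region_id = r$region_id
      )
    })
  })
  if (is.null(cells) || nrow(cells) == 0) {
    cells <- tibble::tibble(
      x = numeric(), y = numeric(), z = numeric(),
      nucleus_radius = numeric(), soma_radius = numeric(),
      !!!setNames(rep(list(numeric()), length(dyes)), paste0("amp_", dyes)),
      region_id = integer()
    )
  }
  cells <- dplyr::mutate(cells, cell_id = dplyr::row_number(),
                         .before = 1)
  new_tissue_phantom(box_um, regions, cells, empty_beads(), seed)
}

empty_beads <- function() {
  tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                 diameter_um = numeric(), amplitude = numeric())
}

new_tissue_phantom <- function(box_um, regions, cells, beads, seed) {
  structure(
    list(box_um = as.numeric(box_um), regions = regions,
         cells = cells, beads = beads, seed = seed),
    class = "tissue_phantom"
  )
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf(
    "<tissue_phantom> box %g x %g x %g um, %d cells in %d region(s), %d bead(s)\n",
    x$box_um[1], x$box_um[2], x$box_um[3], nrow(x$cells),
    nrow(x$regions), nrow(x$beads)
  ))
  invisible(x)
}

#' Generate a bead calibration phantom
#'
#' Emulates fluorescent microbeads embedded in agarose: `n_beads` uniform
#' spheres (default diameter 4 um) placed with a minimum pairwise
#' separation by bounded rejection sampling.
#'
#' @param n_beads number of beads (>= 1).
#' @param box_um phantom extents in micrometres.
#' @param min_separation_um minimum centre-to-centre distance; must exceed
#'   the diameter.
#' @param diameter_um bead diameter (default 4 um).
#' @param amplitude emission amplitude per bead.
#' @param seed integer seed.
#' @param max_tries placement attempts before giving up.
#' @return A `tissue_phantom` with beads only (no cells, no regions).
#' @export
generate_bead_phantom <- function(n_beads, box_um, min_separation_um,
                                  diameter_um = 4, amplitude = 1,
                                  seed = NULL, max_tries = 1000 * n_beads) {
  stopifnot(n_beads >= 1, length(box_um) == 3, all(box_um > 0),
            diameter_um > 0)
  if (min_separation_um <= diameter_um) {
    abort("min_separation_um must exceed the bead diameter")
  }
  r <- diameter_um / 2
  if (any(box_um < diameter_um)) abort("box too small for a bead")
  pts <- with_seed(seed, {
    acc <- matrix(numeric(0), ncol = 3)
    tries <- 0
    while (nrow(acc) < n_beads) {
      tries <- tries + 1
      if (tries > max_tries) {
        abort(sprintf(
          "could not place %d beads at separation %g um in the box",
          n_beads, min_separation_um))
      }
      p <- c(runif(1, r, box_um[1] - r), runif(1, r, box_um[2] - r),
             runif(1, r, box_um[3] - r))
      if (nrow(acc) == 0 ||
          all(sqrt(colSums((t(acc) - p)^2)) >= min_separation_um)) {
        acc <- rbind(acc, p)
      }
    }
    acc
  })
  beads <- tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    diameter_um = diameter_um, amplitude = amplitude
  )
  regions <- tibble::tibble(
    region_id = integer(), name = character(), x0 = numeric(),
    x1 = numeric(), y0 = numeric(), y1 = numeric(), z0 = numeric(),
    z1 = numeric(), density_per_mm3 = numeric(), dye_means = list()
  )
  cells <- generate_tissue_phantom(box_um, region_model(
    1, "empty", c(0, box_um[1]), c(0, box_um[2]), c(0, box_um[3]), 0
  ), seed = 0)$cells
  new_tissue_phantom(box_um, regions, cells, beads, seed)
}

#' Rasterise region labels to a voxel volume
#'
#' @param phantom a `tissue_phantom`.
#' @param spacing_um voxel edge length in micrometres; each voxel takes the
#'   region id at its centre point, background 0.
#' @return Integer 3D array indexed (row = y, col = x, slice = z) with
#'   attribute `spacing_um`.
#' @export
voxelize_labels <- function(phantom, spacing_um) {
  stopifnot(spacing_um > 0)
  dims <- pmax(1L, ceiling(phantom$box_um / spacing_um))
  if (nrow(phantom$regions) > 0) {
    ext <- with(phantom$regions, pmin(x1 - x0, y1 - y0, z1 - z0))
    if (any(spacing_um > ext)) {
      warn("voxel spacing exceeds the smallest region extent; thin regions may vanish")
    }
  }
  xc <- (seq_len(dims[1]) - 0.5) * spacing_um
  yc <- (seq_len(dims[2]) - 0.5) * spacing_um
  zc <- (seq_len(dims[3]) - 0.5) * spacing_um
  vol <- array(0L, dim = c(dims[2], dims[1], dims[3]))
  for (i in seq_len(nrow(phantom$regions))) {
    r <- phantom$regions[i, ]
    ix <- which(xc >= r$x0 & xc < r$x1)
    iy <- which(yc >= r$y0 & yc < r$y1)
    iz <- which(zc >= r$z0 & zc < r$z1)
    vol[iy, ix, iz] <- r$region_id
  }
  structure(vol, spacing_um = spacing_um)
}

#' 2D region-label image at a block face
#'
#' Convenience slice of the region geometry at depth `z_um`, on the same
#' pixel grid as rendered images, for centroid-based region assignment.
#'
#' @param phantom a `tissue_phantom`.
#' @param pixel_size_um lateral pixel size.
#' @param z_um face depth (default 0).
#' @return Integer label matrix (row = y, col = x) with `pixel_size_um`
#'   attribute.
#' @export
region_label_image <- function(phantom, pixel_size_um, z_um = 0) {
  stopifnot(pixel_size_um > 0)
  nx <- max(1L, ceiling(phantom$box_um[1] / pixel_size_um))
  ny <- max(1L, ceiling(phantom$box_um[2] / pixel_size_um))
  xc <- (seq_len(nx) - 0.5) * pixel_size_um
  yc <- (seq_len(ny) - 0.5) * pixel_size_um
  lab <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(phantom$regions))) {
    r <- phantom$regions[i, ]
    if (z_um < r$z0 || z_um >= r$z1) next
    lab[yc >= r$y0 & yc < r$y1, xc >= r$x0 & xc < r$x1] <- r$region_id
  }
  structure(lab, pixel_size_um = pixel_size_um)
}

#' Expected visible cells per section
#'
#' Under surface excitation only material down to the 1/e-style cutoff
#' depth below each block face is imaged: a cell at depth z below face k is
#' expected-visible when exp(-z/d) >= `visibility_cutoff`, i.e. z < z* with
#' z* = -d log(cutoff). With section thickness > z* no cell is visible in
#' more than one section.
#'
#' @param phantom a `tissue_phantom`.
#' @param schedule a [schedule_sections()] result.
#' @param d_um attenuation (1/e) depth in micrometres.
#' @param visibility_cutoff relative-intensity cutoff in (0, 1);
#'   default `exp(-1)`.
#' @return Tibble (`section_index`, `cell_id`, `depth_um`, `region_id`).
#' @export
ground_truth_section_table <- function(phantom, schedule, d_um,
                                       visibility_cutoff = exp(-1)) {
  stopifnot(d_um > 0, visibility_cutoff > 0, visibility_cutoff < 1 ||
              visibility_cutoff == 1)
  z_star <- -d_um * log(visibility_cutoff)
  purrr::map_dfr(seq_len(nrow(schedule$faces)), function(k) {
    fz <- schedule$faces$face_z_um[k]
    depth <- phantom$cells$z - fz
    vis <- depth >= 0 & depth < z_star
    if (!any(vis)) return(NULL)
    tibble::tibble(
      section_index = schedule$faces$section_index[k],
      cell_id = phantom$cells$cell_id[vis],
      depth_um = depth[vis],
      region_id = phantom$cells$region_id[vis]
    )
  })
}
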