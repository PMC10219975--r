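# Cell segmentation, regional counting/density, hierarchy aggregation and
# the accompanying statistics.

#' Segment cells on a block-face image
#'
#' Deterministic surrogate for interactive nuclei counting:
#' Gaussian smooth, Otsu threshold, hole filling, an intensity-guided
#' watershed to split touching cells (nuclei are intensity peaks, so the
#' smoothed-intensity surface separates overlapping projections that a
#' distance map cannot), then an area filter. Intended for a single
#' channel; by convention the red (propidium-iodide) channel carries the
#' Nissl-like signal used for counting.
#'
#' @param image single-channel matrix, or RGB array (segmented on
#'   `channel`). Needs a `pixel_size_um` attribute unless given.
#' @param pixel_size_um um per px (overrides the attribute).
#' @param channel channel for RGB input (default `"R"`).
#' @param smooth_sigma_um pre-smoothing sd (default 1.5 um).
#' @param min_area_um2,max_area_um2 area filter bounds.
#' @param watershed_tolerance watershed merge tolerance in normalised
#'   intensity units (0-1); smaller splits more aggressively.
#' @param section_index carried into the cell records.
#' @return List with `labels` (integer matrix) and `cells` tibble
#'   (`label`, `x_um`, `y_um`, `area_um2`, `median_intensity`,
#'   `mean_intensity`, per-channel medians for RGB input,
#'   `section_index`).
#' @export
segment_cells <- function(image, pixel_size_um = NULL, channel = "R",
                          smooth_sigma_um = 1.5,
                          min_area_um2 = 15, max_area_um2 = 400,
                          watershed_tolerance = 0.05,
                          section_index = NA_integer_) {
  pixel_size_um <- pixel_size_um %||% attr(image, "pixel_size_um") %||%
    abort("pixel_size_um required")
  m <- to_gray(image, channel)
  empty <- list(
    labels = matrix(0L, nrow(m), ncol(m)),
    cells = tibble::tibble(
      label = integer(), x_um = numeric(), y_um = numeric(),
      area_um2 = numeric(), median_intensity = numeric(),
      mean_intensity = numeric(), section_index = integer()
    )
  )
  rng <- range(m)
  if (diff(rng) == 0) return(empty)
  sm <- smooth2d(m, smooth_sigma_um / pixel_size_um)
  norm <- (sm - min(sm)) / diff(range(sm))
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  # an Otsu split of pure background selects about half the frame;
  # genuine sparse nuclei never do
  if (mean(mask) > 0.4) return(empty)
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1)))
  labels <- EBImage::watershed(EBImage::Image(norm * mask),
                               tolerance = watershed_tolerance)
  lab <- as.matrix(EBImage::imageData(labels))
  storage.mode(lab) <- "integer"
  px_area <- pixel_size_um^2
  tab <- tabulate(lab[lab > 0])
  keep_ids <- which(tab * px_area >= min_area_um2 &
                      tab * px_area <= max_area_um2)
  lab[!(lab %in% keep_ids)] <- 0L
  if (length(keep_ids) == 0) return(empty)
  # relabel 1..n in raster order of first occurrence
  lab_f <- factor(lab[lab > 0], levels = keep_ids)
  new_ids <- seq_along(keep_ids)
  lab[lab > 0] <- new_ids[as.integer(lab_f)]
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  vals <- m[lab > 0]
  agg <- tibble::tibble(
    label = ids,
    x_um = (idx[, 2] - 0.5) * pixel_size_um,
    y_um = (idx[, 1] - 0.5) * pixel_size_um,
    v = vals
  ) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      x_um = mean(.data$x_um), y_um = mean(.data$y_um),
      area_um2 = dplyr::n() * px_area,
      median_intensity = median(.data$v),
      mean_intensity = mean(.data$v),
      .groups = "drop"
    ) |>
    dplyr::mutate(section_index = section_index)
  if (length(dim(image)) == 3L && dim(image)[3] == 3L) {
    for (ch in c("R", "G", "B")) {
      cm <- image_channel(image, ch)
      agg[[paste0("median_", ch)]] <- as.numeric(
        tapply(cm[lab > 0], ids, median))
    }
  }
  list(labels = lab, cells = agg)
}

#' Assign cells to atlas regions
#'
#' Region id is the label at each cell's centroid pixel; centroids outside
#' the label image get region 0 (unassigned).
#'
#' @param cells tibble with `x_um`, `y_um` (mosaic frame).
#' @param label_image integer region-label matrix co-registered with the
#'   mosaic (see [region_label_image()]).
#' @param pixel_size_um um per px of the label image (overrides its
#'   attribute).
#' @param region_names optional tibble (`region_id`, `name`).
#' @return `cells` with `region_id` (and `region_name`) columns added.
#' @export
assign_regions <- function(cells, label_image, pixel_size_um = NULL,
                           region_names = NULL) {
  pixel_size_um <- pixel_size_um %||% attr(label_image, "pixel_size_um") %||%
    abort("pixel_size_um required for the label image")
  H <- nrow(label_image); W <- ncol(label_image)
  i <- round(cells$x_um / pixel_size_um + 0.5)
  j <- round(cells$y_um / pixel_size_um + 0.5)
  inside <- i >= 1 & i <= W & j >= 1 & j <= H
  rid <- integer(nrow(cells))
  rid[inside] <- label_image[cbind(j[inside], i[inside])]
  out <- dplyr::mutate(cells, region_id = as.integer(rid))
  if (!is.null(region_names)) {
    out <- dplyr::left_join(
      out, dplyr::select(region_names, "region_id", region_name = "name"),
      by = "region_id")
  }
  out
}

#' Region areas from a label image
#'
#' @param label_image integer region-label matrix.
#' @param pixel_size_um um per px.
#' @return Tibble (`region_id`, `area_mm2`), excluding background.
#' @export
region_areas_from_labels <- function(label_image, pixel_size_um = NULL) {
  pixel_size_um <- pixel_size_um %||% attr(label_image, "pixel_size_um") %||%
    abort("pixel_size_um required")
  ids <- sort(unique(as.integer(label_image[label_image > 0])))
  tibble::tibble(
    region_id = ids,
    area_mm2 = vapply(ids, function(r) sum(label_image == r), numeric(1)) *
      (pixel_size_um / 1000)^2
  )
}

#' Per-section regional counts and densities
#'
#' @param cells tibble with `section_index` and `region_id` per cell.
#' @param region_areas tibble (`region_id`, `area_mm2`), optionally per
#'   `section_index`.
#' @return A `region_counts` tibble: one row per (section, region) with
#'   `n_cells`, `area_mm2` and `density_per_mm2` (areal density, as counts
#'   are per imaged face). Unassigned cells (region 0) keep NA area.
#' @export
count_and_density <- function(cells, region_areas) {
  counts <- cells |>
    dplyr::count(.data$section_index, .data$region_id, name = "n_cells")
  sections <- unique(cells$section_index)
  grid <- tidyr::expand_grid(
    section_index = sections,
    region_id = unique(c(region_areas$region_id, counts$region_id))
  )
  by <- if ("section_index" %in% names(region_areas)) {
    c("section_index", "region_id")
  } else {
    "region_id"
  }
  out <- grid |>
    dplyr::left_join(counts, by = c("section_index", "region_id")) |>
    dplyr::mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L)) |>
    dplyr::left_join(region_areas, by = by)
  bad <- !is.na(out$area_mm2) & out$area_mm2 <= 0 & out$n_cells > 0
  if (any(bad)) abort("region with zero area but nonzero count: label/registration mismatch")
  out <- dplyr::mutate(out,
    density_per_mm2 = ifelse(is.na(.data$area_mm2) | .data$area_mm2 == 0,
                             NA_real_, .data$n_cells / .data$area_mm2))
  class(out) <- c("region_counts", class(out))
  out
}

#' Aggregate counts over a region hierarchy
#'
#' Rolls leaf counts up a rooted region tree: each node's total is its own
#' count plus all descendants', with percentages of the root — the table
#' behind a sunburst plot of regional composition.
#'
#' @param counts tibble (`node`, `count`) of own counts per node; nodes
#'   absent from `counts` get 0.
#' @param tree tibble (`node`, `parent`); the root has `parent` NA.
#' @return Tibble (`node`, `parent`, `own_count`, `total_count`,
#'   `pct_parent`, `pct_root`), root first.
#' @export
aggregate_region_tree <- function(counts, tree) {
  stopifnot(all(c("node", "parent") %in% names(tree)))
  tree$node <- as.character(tree$node)
  tree$parent <- as.character(tree$parent)
  if (nrow(counts)) counts$node <- as.character(counts$node)
  root <- tree$node[is.na(tree$parent)]
  if (length(root) != 1) abort("tree must have exactly one root")
  if (anyDuplicated(tree$node)) abort("duplicate nodes in tree")
  unknown <- setdiff(counts$node, tree$node)
  if (length(unknown)) {
    abort(paste("counted nodes missing from tree:",
                paste(unknown, collapse = ", ")))
  }
  own <- setNames(rep(0, nrow(tree)), tree$node)
  if (nrow(counts)) own[as.character(counts$node)] <- counts$count
  kids <- split(tree$node, tree$parent)
  total <- setNames(rep(NA_real_, nrow(tree)), tree$node)
  visiting <- character()
  roll <- function(node) {
    if (node %in% visiting) abort("cycle in region tree")
    visiting <<- c(visiting, node)
    ch <- kids[[node]]
    tot <- own[[node]] +
      if (is.null(ch)) 0 else sum(vapply(ch, roll, numeric(1)))
    visiting <<- setdiff(visiting, node)
    total[[node]] <<- tot
    tot
  }
  root_total <- roll(root)
  # orphaned subtrees (parent not in tree) indicate a malformed hierarchy
  if (any(is.na(total))) abort("tree contains nodes unreachable from the root")
  parent_total <- total[match(tree$parent, tree$node)]
  out <- tibble::tibble(
    node = tree$node, parent = tree$parent,
    own_count = unname(own[tree$node]),
    total_count = unname(total[tree$node]),
    pct_parent = ifelse(is.na(parent_total) | parent_total == 0, NA_real_,
                        100 * unname(total[tree$node]) / parent_total),
    pct_root = if (root_total > 0) 100 * unname(total[tree$node]) / root_total
               else NA_real_
  )
  dplyr::arrange(out, dplyr::desc(.data$total_count))
}

#' Two-tailed paired t test
#'
#' Implemented from the defining formula: t = mean(d) / (sd(d)/sqrt(n))
#' on the paired differences, df = n - 1 (so ten paired sections give
#' df = 9), two-tailed p from the t distribution.
#'
#' @param series_a,series_b equal-length numeric vectors (>= 2 pairs).
#' @return Tibble (`statistic`, `df`, `p_value`, `mean_diff`, `n`,
#'   `method`, `flagged`); zero-variance differences flag the result with
#'   NA statistic.
#' @export
paired_t <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) abort("series lengths differ")
  n <- length(series_a)
  if (n < 2) abort("need at least 2 pairs")
  d <- series_a - series_b
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) {
      # identical series: no evidence of difference
      return(tibble::tibble(statistic = 0, df = n - 1, p_value = 1,
                            mean_diff = 0, n = n,
                            method = "paired t", flagged = FALSE))
    }
    warn("zero-variance nonzero differences: t undefined")
    return(tibble::tibble(statistic = NA_real_, df = n - 1,
                          p_value = NA_real_, mean_diff = mean(d), n = n,
                          method = "paired t", flagged = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  tibble::tibble(
    statistic = t_stat, df = n - 1,
    p_value = 2 * pt(-abs(t_stat), df = n - 1),
    mean_diff = mean(d), n = n, method = "paired t", flagged = FALSE
  )
}

#' Multi-group statistics: Welch ANOVA, Tukey HSD, Shapiro-Wilk
#'
#' Welch's one-way ANOVA (Satterthwaite denominator df, so fractional df2
#' is expected), Tukey honestly-significant-difference pairwise
#' comparisons, and a Shapiro-Wilk normality test on the pooled values.
#'
#' @param values numeric vector.
#' @param group grouping factor/vector (>= 2 groups, each n >= 2).
#' @return A `stat_report`: list of tibbles `welch` (`F`, `df1`, `df2`,
#'   `p_value`), `tukey` (`pair`, `diff`, `lwr`, `upr`, `p_adj`),
#'   `shapiro` (`W`, `p_value`) and `flagged`.
#' @export
group_stats <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) abort("need at least 2 groups")
  ns <- table(group)
  if (any(ns < 2)) abort("every group needs n >= 2")
  vars <- tapply(values, group, var)
  flagged <- any(vars == 0)
  welch <- if (flagged) {
    warn("zero-variance group: Welch ANOVA undefined")
    tibble::tibble(F = NA_real_, df1 = nlevels(group) - 1,
                   df2 = NA_real_, p_value = NA_real_)
  } else {
    w <- oneway.test(values ~ group, var.equal = FALSE)
    tibble::tibble(F = unname(w$statistic), df1 = unname(w$parameter[1]),
                   df2 = unname(w$parameter[2]),
                   p_value = unname(w$p.value))
  }
  tk <- TukeyHSD(aov(values ~ group))$group
  tukey <- tibble::tibble(
    pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"]
  )
  sw <- tryCatch(shapiro.test(values), error = function(e) NULL)
  shapiro <- if (is.null(sw)) {
    tibble::tibble(W = NA_real_, p_value = NA_real_)
  } else {
    tibble::tibble(W = unname(sw$statistic), p_value = unname(sw$p.value))
  }
  structure(list(welch = welch, tukey = tukey, shapiro = shapiro,
                 flagged = flagged),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  w <- x$welch
  cat(sprintf("<stat_report> Welch F(%s, %s) = %s, p = %s%s\n",
              format(w$df1), format(round(w$df2, 1)),
              format(signif(w$F, 4)), format(signif(w$p_value, 3)),
              if (x$flagged) " [flagged: zero-variance group]" else ""))
  cat(sprintf("  Shapiro-Wilk W = %s, p = %s; %d Tukey pair(s)\n",
              format(signif(x$shapiro$W, 4)),
              format(signif(x$shapiro$p_value, 3)), nrow(x$tukey)))
  invisible(x)
}
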