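# Tile registration by phase correlation and mosaic assembly.

to_gray <- function(image, channel = "R") {
  if (length(dim(image)) == 3L) image_channel(image, channel) else unclass(image)
}

hann2d <- function(H, W) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(H) - 1) / (H - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(W) - 1) / (W - 1))
  outer(wy, wx)
}

# Wrap a 0-based FFT index to a signed shift in [-N/2, N/2).
signed_shift <- function(idx0, N) ifelse(idx0 >= N / 2, idx0 - N, idx0)

#' Estimate the translation between two overlapping tiles
#'
#' Phase correlation: the normalised cross-power spectrum of the two
#' (Hann-windowed) tiles has its inverse-FFT peak at the integer
#' translation between them. The search is restricted to a radius around
#' the nominal offset from the tile plan; when the peak is not decisive
#' (ratio of best to second-best peak below `min_confidence`) the nominal
#' offset is returned with a warning.
#'
#' Offsets follow the tile-origin convention: the returned `(dx, dy)` is
#' the position of `tile_b`'s origin relative to `tile_a`'s origin, in
#' pixels (x = columns, y = rows).
#'
#' @param tile_a,tile_b images of identical shape.
#' @param nominal_offset_px numeric (dx, dy) from the tile plan.
#' @param search_radius_px maximum deviation from nominal considered.
#' @param min_confidence peak-ratio threshold below which the estimate
#'   falls back to nominal.
#' @param channel channel used for RGB tiles.
#' @return List `dx`, `dy` (integers), `confidence` (peak ratio) and
#'   `fallback` (logical).
#' @export
estimate_offset <- function(tile_a, tile_b, nominal_offset_px,
                            search_radius_px = 15, min_confidence = 1.3,
                            channel = "R") {
  a <- to_gray(tile_a, channel); b <- to_gray(tile_b, channel)
  if (!all(dim(a) == dim(b))) abort("tiles must share one shape")
  H <- nrow(a); W <- ncol(a)
  ndx <- round(nominal_offset_px[1]); ndy <- round(nominal_offset_px[2])
  nominal <- list(dx = as.integer(ndx), dy = as.integer(ndy))
  # crop both tiles to the nominal overlap; the phase-correlation peak is
  # then the residual around the nominal offset, immune to FFT aliasing
  # when the true offset exceeds half the tile size
  a_cols <- max(1, ndx + 1):min(W, ndx + W)
  a_rows <- max(1, ndy + 1):min(H, ndy + H)
  if (length(a_cols) < 0.1 * W || length(a_rows) < 0.1 * H) {
    abort("tiles share less than 10% nominal overlap")
  }
  wa <- a[a_rows, a_cols, drop = FALSE]
  wb <- b[a_rows - ndy, a_cols - ndx, drop = FALSE]
  h <- nrow(wa); w_ <- ncol(wa)
  win <- hann2d(h, w_)
  fa <- fft((wa - mean(wa)) * win)
  fb <- fft((wb - mean(wb)) * win)
  cp <- fa * Conj(fb)
  cp <- cp / (Mod(cp) + 1e-12)
  surf <- Re(fft(cp, inverse = TRUE)) / length(cp)
  iy <- signed_shift(matrix(0:(h - 1), h, w_), h)
  ix <- signed_shift(matrix(0:(w_ - 1), h, w_, byrow = TRUE), w_)
  within <- abs(ix) <= search_radius_px & abs(iy) <= search_radius_px
  cand <- surf
  cand[!within] <- -Inf
  peak_idx <- which.max(cand)
  peak <- cand[peak_idx]
  rdy <- iy[peak_idx]; rdx <- ix[peak_idx]
  # second peak outside a 3-px neighbourhood of the first
  near <- abs(ix - rdx) <= 3 & abs(iy - rdy) <= 3
  cand[near] <- -Inf
  second <- max(cand[is.finite(cand)], -Inf)
  noise_floor <- stats::sd(surf) + 1e-12
  confidence <- if (is.finite(second) && second > noise_floor) {
    peak / second
  } else {
    peak / noise_floor
  }
  if (!is.finite(confidence) || confidence < min_confidence || peak <= 0) {
    warn("indecisive phase-correlation peak: falling back to nominal offset")
    return(list(dx = nominal$dx, dy = nominal$dy,
                confidence = confidence, fallback = TRUE))
  }
  list(dx = as.integer(ndx + rdx), dy = as.integer(ndy + rdy),
       confidence = confidence, fallback = FALSE)
}

# Adjacent (rook) pairs of a tile plan, as rows of (from, to) tile ids.
adjacent_pairs <- function(tile_plan) {
  t <- tile_plan$tiles
  pairs <- list()
  for (i in seq_len(nrow(t))) {
    right <- which(t$row == t$row[i] & t$col == t$col[i] + 1)
    below <- which(t$row == t$row[i] + 1 & t$col == t$col[i])
    for (j in c(right, below)) {
      pairs[[length(pairs) + 1]] <- c(t$tile_id[i], t$tile_id[j])
    }
  }
  do.call(rbind, pairs)
}

#' Estimate offsets for every adjacent tile pair of a plan
#'
#' @param tiles named or ordered list of tile images in `tile_id` order.
#' @param tile_plan a [plan_tiles()] result.
#' @param pixel_size_um um per px, to convert plan origins to pixels.
#' @param ... passed to [estimate_offset()].
#' @return Tibble (`from`, `to`, `dx`, `dy`, `confidence`, `fallback`).
#' @export
estimate_pair_offsets <- function(tiles, tile_plan, pixel_size_um, ...) {
  pairs <- adjacent_pairs(tile_plan)
  t <- tile_plan$tiles
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ti <- t[t$tile_id == i, ]; tj <- t[t$tile_id == j, ]
    nominal <- c((tj$x_mm - ti$x_mm), (tj$y_mm - ti$y_mm)) * 1000 /
      pixel_size_um
    est <- estimate_offset(tiles[[i]], tiles[[j]], nominal, ...)
    tibble::tibble(from = i, to = j, dx = est$dx, dy = est$dy,
                   confidence = est$confidence, fallback = est$fallback)
  })
}

#' Assemble a mosaic from registered tiles
#'
#' Places tiles at global positions obtained by accumulating the measured
#' pairwise offsets along a maximum-confidence spanning tree anchored at
#' the first tile's nominal position, then fuses them with linear feather
#' blending in the overlaps. Loop-closure residuals beyond
#' `loop_tolerance_px` trigger one neighbour-averaging relaxation pass
#' with a warning.
#'
#' @param tiles list of tile images in `tile_id` order.
#' @param tile_plan a [plan_tiles()] result.
#' @param offsets tibble from [estimate_pair_offsets()]; NULL uses the
#'   nominal grid.
#' @param pixel_size_um um per px.
#' @param loop_tolerance_px allowed loop-closure residual.
#' @return List with `mosaic` (matrix or RGB array, integer grey levels)
#'   and `placement` tibble (`tile_id`, `row`, `col`, `x_px`, `y_px`,
#'   `confidence`).
#' @export
assemble_mosaic <- function(tiles, tile_plan, offsets = NULL,
                            pixel_size_um = NULL, loop_tolerance_px = 3) {
  t <- tile_plan$tiles
  n <- nrow(t)
  pixel_size_um <- pixel_size_um %||%
    attr(tiles[[1]], "pixel_size_um") %||%
    abort("pixel_size_um required")
  nominal <- cbind(t$x_mm, t$y_mm) * 1000 / pixel_size_um
  nominal <- round(nominal - matrix(nominal[1, ], n, 2, byrow = TRUE))
  pos <- nominal
  conf <- rep(NA_real_, n)
  if (!is.null(offsets) && n > 1 && nrow(offsets) > 0) {
    # maximum-confidence spanning tree (Kruskal with union-find)
    ord <- order(-offsets$confidence)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    tree <- list()
    for (k in ord) {
      a <- find(offsets$from[k]); b <- find(offsets$to[k])
      if (a != b) {
        parent[a] <- b
        tree[[length(tree) + 1]] <- offsets[k, ]
      }
    }
    tree <- dplyr::bind_rows(tree)
    pos <- matrix(NA_real_, n, 2)
    pos[1, ] <- nominal[1, ]
    repeat {
      progressed <- FALSE
      for (k in seq_len(nrow(tree))) {
        e <- tree[k, ]
        if (!is.na(pos[e$from, 1]) && is.na(pos[e$to, 1])) {
          pos[e$to, ] <- pos[e$from, ] + c(e$dx, e$dy)
          conf[e$to] <- e$confidence
          progressed <- TRUE
        } else if (!is.na(pos[e$to, 1]) && is.na(pos[e$from, 1])) {
          pos[e$from, ] <- pos[e$to, ] - c(e$dx, e$dy)
          conf[e$from] <- e$confidence
          progressed <- TRUE
        }
      }
      if (!progressed) break
    }
    pos[is.na(pos[, 1]), ] <- nominal[is.na(pos[, 1]), , drop = FALSE]
    resid <- apply(offsets, 1, function(e) {
      max(abs(pos[e[["to"]], ] - pos[e[["from"]], ] -
                c(e[["dx"]], e[["dy"]])))
    })
    if (any(resid > loop_tolerance_px)) {
      warn("loop-closure residuals beyond tolerance: averaging placements")
      new_pos <- pos
      for (i in seq(2, n)) {
        est <- list()
        for (k in seq_len(nrow(offsets))) {
          e <- offsets[k, ]
          if (e$to == i) est[[length(est) + 1]] <- pos[e$from, ] + c(e$dx, e$dy)
          if (e$from == i) est[[length(est) + 1]] <- pos[e$to, ] - c(e$dx, e$dy)
        }
        if (length(est)) new_pos[i, ] <- round(colMeans(do.call(rbind, est)))
      }
      pos <- new_pos
    }
  }
  pos <- pos - matrix(apply(pos, 2, min), n, 2, byrow = TRUE)
  dims1 <- dim(tiles[[1]])
  Wt <- dims1[2]; Ht <- dims1[1]
  n_ch <- if (length(dims1) == 3L) dims1[3] else 1L
  Wm <- max(pos[, 1]) + Wt
  Hm <- max(pos[, 2]) + Ht
  margin_x <- max(1, round(tile_plan$overlap_fraction *
                             tile_plan$fov_mm[1] * 1000 / pixel_size_um))
  margin_y <- max(1, round(tile_plan$overlap_fraction *
                             tile_plan$fov_mm[2] * 1000 / pixel_size_um))
  wx <- pmin(1, pmin(seq_len(Wt), Wt + 1 - seq_len(Wt)) / margin_x)
  wy <- pmin(1, pmin(seq_len(Ht), Ht + 1 - seq_len(Ht)) / margin_y)
  wt <- outer(wy, wx)
  acc <- array(0, dim = c(Hm, Wm, n_ch))
  wacc <- matrix(0, Hm, Wm)
  for (i in seq_len(n)) {
    px <- as_channel_stack(tiles[[i]])
    rows <- pos[i, 2] + seq_len(Ht)
    cols <- pos[i, 1] + seq_len(Wt)
    for (ch in seq_len(n_ch)) {
      acc[rows, cols, ch] <- acc[rows, cols, ch] + wt * px[, , ch]
    }
    wacc[rows, cols] <- wacc[rows, cols] + wt
  }
  wacc[wacc == 0] <- 1
  for (ch in seq_len(n_ch)) acc[, , ch] <- round(acc[, , ch] / wacc)
  mosaic <- if (n_ch == 1L) acc[, , 1] else acc
  attr(mosaic, "pixel_size_um") <- pixel_size_um
  attr(mosaic, "bit_depth") <- attr(tiles[[1]], "bit_depth")
  list(
    mosaic = mosaic,
    placement = tibble::tibble(
      tile_id = t$tile_id, row = t$row, col = t$col,
      x_px = pos[, 1], y_px = pos[, 2], confidence = conf
    )
  )
}

#' Stitch one section of an acquisition series
#'
#' Convenience wrapper: estimates pairwise offsets for the section's tiles
#' and assembles the feather-blended mosaic.
#'
#' @param series a [run_virtual_acquisition()] result.
#' @param section_index which section to stitch.
#' @param refine estimate offsets by phase correlation (TRUE) or trust the
#'   nominal grid (FALSE)?
#' @param ... passed to [estimate_pair_offsets()].
#' @return As [assemble_mosaic()], plus the section's `face_z_um`.
#' @export
stitch_section <- function(series, section_index, refine = TRUE, ...) {
  man <- dplyr::filter(series$manifest,
                       .data$section_index == !!section_index)
  if (nrow(man) == 0) abort("no such section in the series")
  man <- dplyr::arrange(man, .data$tile_id)
  tiles <- series$images[man$key]
  pix <- series$config$pixel_size_um
  offsets <- NULL
  if (refine && nrow(man) > 1) {
    offsets <- estimate_pair_offsets(tiles, series$tile_plan, pix, ...)
  }
  out <- assemble_mosaic(tiles, series$tile_plan, offsets, pix)
  out$face_z_um <- man$face_z_um[1]
  out$section_index <- section_index
  out
}
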