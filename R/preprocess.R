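# Per-image corrections applied before stitching and quantification.

as_channel_stack <- function(image) {
  if (length(dim(image)) == 2L) {
    array(image, dim = c(dim(image), 1L))
  } else {
    unclass(image)
  }
}

#' Flat-field correction
#'
#' Divides an image by a smooth illumination gain field and rescales by
#' the field mean, so a uniform scene keeps its global mean. The field may
#' be single-channel (applied to all channels) or per-channel.
#'
#' @param image matrix or rows x cols x c array.
#' @param field positive gain raster, same spatial shape.
#' @param eps floor applied to non-positive field pixels (with a warning).
#' @return Corrected image of the original shape and attributes.
#' @export
flat_field_correct <- function(image, field, eps = 1e-3) {
  f <- unclass(field)
  if (!all(dim(f)[1:2] == dim(image)[1:2])) {
    abort("field and image shapes differ")
  }
  if (any(f <= 0)) {
    warn("non-positive flat-field pixels floored")
    f[f <= 0] <- eps
  }
  st <- as_channel_stack(image)
  fc <- if (length(dim(f)) == 3L) f else array(f, dim = dim(st))
  out <- st / fc * mean(f)
  if (length(dim(image)) == 2L) out <- out[, , 1]
  attributes(out) <- utils::modifyList(attributes(image) %||% list(),
                                       list(dim = dim(out)))
  out
}

#' Estimate a flat-field model from a tile collection
#'
#' Per-pixel median across at least 10 tiles (sparse foreground averages
#' out), Gaussian-smoothed with sd = 5% of the field width, normalised to
#' mean 1.
#'
#' @param tiles list of images sharing one shape (matrices or RGB arrays).
#' @param channel channel used when tiles are RGB (default `"R"`).
#' @return A `flat_field_model`: list with `field` (matrix, mean 1) and
#'   `n_tiles`.
#' @export
estimate_flat_field <- function(tiles, channel = "R") {
  if (length(tiles) < 10) {
    abort("need >= 10 tiles to estimate a flat field; supply an explicit reference instead")
  }
  mats <- lapply(tiles, function(t) {
    if (length(dim(t)) == 3L) image_channel(t, channel) else unclass(t)
  })
  dims <- dim(mats[[1]])
  stack <- array(unlist(mats), dim = c(dims, length(mats)))
  med <- apply(stack, c(1, 2), median)
  sm <- smooth2d(med, sigma_px = 0.05 * dims[2])
  field <- sm / mean(sm)
  structure(list(field = field, n_tiles = length(tiles)),
            class = "flat_field_model")
}

#' Colour correction: white balance or spectral unmixing
#'
#' With a length-3 gain vector this is per-channel white balance; with an
#' invertible 3 x 3 matrix the per-pixel linear map `M %*% rgb` is applied
#' — passing the inverse of the optics mixing matrix recovers dye
#' abundance images (unmixing).
#'
#' @param rgb rows x cols x 3 array.
#' @param gains positive length-3 vector, or a 3 x 3 matrix.
#' @return Corrected array, same shape and attributes.
#' @export
color_correct <- function(rgb, gains) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    abort("rgb must be a rows x cols x 3 array")
  }
  if (is.matrix(gains)) {
    if (!all(dim(gains) == c(3, 3))) abort("matrix must be 3 x 3")
    if (abs(det(gains)) < 1e-12) abort("singular colour-correction matrix")
    M <- gains
  } else {
    if (length(gains) != 3 || any(gains <= 0)) {
      abort("gains must be 3 positive values")
    }
    M <- diag(gains)
  }
  flat <- matrix(unclass(rgb), ncol = 3)
  out <- array(flat %*% t(M), dim = dim(rgb))
  attributes(out) <- utils::modifyList(attributes(rgb) %||% list(),
                                       list(dim = dim(out)))
  out
}

#' Extended depth of focus
#'
#' Fuses a focal stack into one image. The default picks, per pixel, the
#' slice with the highest local intensity variance (window 9 px), a focus
#' measure suited to sparse punctate signal; `method = "max"` is a plain
#' maximum projection.
#'
#' @param stack list of matrices, or a rows x cols x n array.
#' @param method `"variance"` (default) or `"max"`.
#' @param window odd local-variance window size in px.
#' @return Single fused matrix.
#' @export
extended_depth_of_focus <- function(stack, method = c("variance", "max"),
                                    window = 9L) {
  method <- match.arg(method)
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  }
  if (length(stack) == 0) abort("empty stack")
  if (length(stack) == 1) return(stack[[1]])
  if (method == "max") {
    return(Reduce(pmax, stack))
  }
  box <- matrix(1 / window^2, window, window)
  local_var <- lapply(stack, function(m) {
    mi <- EBImage::Image(m)
    mu <- EBImage::filter2(mi, box, boundary = "replicate")
    mu2 <- EBImage::filter2(mi^2, box, boundary = "replicate")
    as.matrix(mu2 - mu^2)
  })
  dims <- dim(stack[[1]])
  pick <- matrix(1L, dims[1], dims[2])
  best <- local_var[[1]]
  for (k in seq_along(stack)[-1]) {
    better <- local_var[[k]] > best
    pick[better] <- k
    best[better] <- local_var[[k]][better]
  }
  out <- stack[[1]]
  for (k in seq_along(stack)[-1]) {
    sel <- pick == k
    out[sel] <- stack[[k]][sel]
  }
  out
}

#' Lossless 8-to-16-bit conversion
#'
#' Multiplies by 257 so that 0 maps to 0 and 255 to 65535, spanning the
#' full 16-bit range while remaining exactly invertible.
#'
#' @param image8 integer-valued image in \[0, 255\].
#' @return Image scaled to \[0, 65535\] with `bit_depth` attribute 16.
#' @export
to_16bit <- function(image8) {
  v <- unclass(image8)
  bd <- attr(image8, "bit_depth")
  if (!is.null(bd) && bd != 8L) abort("input is not 8-bit")
  if (any(v < 0) || any(v > 255) || any(v != round(v))) {
    abort("input is not 8-bit integer data")
  }
  out <- v * 257
  attributes(out) <- utils::modifyList(attributes(image8) %||% list(),
                                       list(dim = dim(out)))
  attr(out, "bit_depth") <- 16L
  out
}
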