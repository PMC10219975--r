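# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive a reproducible 32-bit substream seed from a root seed and a stage
# name, so every pipeline stage draws from its own named stream.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Clip then round-half-even to the range of a bit depth. base::round()
# is IEC 60559 round-half-even, which is the quantisation contract.
quantize <- function(x, bit_depth) {
  stopifnot(bit_depth %in% c(8L, 16L))
  top <- 2^bit_depth - 1
  round(pmin(pmax(x, 0), top))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Gaussian FWHM conversion constant 2*sqrt(2*log(2)).
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

# 2D Gaussian smoothing of a plain matrix with replicated borders;
# input/output are base matrices.
smooth2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k1 <- exp(-((-half:half)^2) / (2 * sigma_px^2))
  k <- outer(k1, k1)
  out <- EBImage::filter2(EBImage::Image(m), k / sum(k),
                          boundary = "replicate")
  matrix(EBImage::imageData(out), nrow = nrow(m))
}

new_blockface_image <- function(px, tile_origin_um, face_z_um,
                                section_index, pixel_size_um, bit_depth,
                                channels = c("R", "G", "B")) {
  structure(px,
    tile_origin_um = tile_origin_um,
    face_z_um = face_z_um,
    section_index = section_index,
    pixel_size_um = pixel_size_um,
    bit_depth = bit_depth,
    channels = channels,
    class = c("blockface_image", class(px))
  )
}

#' @export
print.blockface_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<blockface_image> %d x %d px x %d channel(s), %g um/px, face z = %g um, section %s\n",
    d[1], d[2], if (length(d) > 2) d[3] else 1L,
    attr(x, "pixel_size_um"), attr(x, "face_z_um"),
    as.character(attr(x, "section_index") %||% NA)
  ))
  invisible(x)
}

# Extract one channel of an RGB block-face image as a plain matrix.
#' Extract a single channel from an RGB image
#'
#' @param image three-channel array (rows x cols x 3).
#' @param channel `"R"`, `"G"` or `"B"` (case-insensitive), or an index.
#' @return A numeric matrix keeping the image's spatial metadata attributes.
#' @export
image_channel <- function(image, channel = "R") {
  stopifnot(length(dim(image)) == 3L)
  idx <- if (is.character(channel)) {
    match(toupper(channel), c("R", "G", "B"))
  } else {
    as.integer(channel)
  }
  if (is.na(idx) || idx < 1 || idx > dim(image)[3]) {
    abort("unknown channel")
  }
  out <- image[, , idx]
  for (a in c("tile_origin_um", "face_z_um", "section_index",
              "pixel_size_um", "bit_depth")) {
    attr(out, a) <- attr(image, a)
  }
  out
}
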