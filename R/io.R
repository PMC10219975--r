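# TIFF and YAML I/O helpers.

#' Write an image as TIFF
#'
#' Integer images at the stated bit depth are scaled to the \[0, 1\] range
#' the TIFF writer expects and written at that bit depth; spatial metadata
#' is stored in a YAML sidecar (`<file>.yaml`) when `sidecar = TRUE`.
#'
#' @param image matrix or rows x cols x 3 array, integer-valued at
#'   `bit_depth`.
#' @param file output path.
#' @param bit_depth 8 or 16; taken from the image attribute when present.
#' @param sidecar write a YAML sidecar with tile origin / face z metadata?
#' @return `file`, invisibly.
#' @export
write_image_tiff <- function(image, file, bit_depth = NULL,
                             sidecar = TRUE) {
  bit_depth <- bit_depth %||% attr(image, "bit_depth") %||% 8L
  top <- 2^bit_depth - 1
  px <- unclass(image) / top
  px[px < 0] <- 0; px[px > 1] <- 1
  tiff::writeTIFF(px, file, bits.per.sample = bit_depth)
  if (sidecar) {
    meta <- list(
      bit_depth = as.integer(bit_depth),
      pixel_size_um = as.numeric(attr(image, "pixel_size_um") %||% NA),
      tile_origin_um = as.numeric(attr(image, "tile_origin_um") %||% c(NA, NA)),
      face_z_um = as.numeric(attr(image, "face_z_um") %||% NA),
      section_index = as.integer(attr(image, "section_index") %||% NA)
    )
    yaml::write_yaml(meta, paste0(file, ".yaml"))
  }
  invisible(file)
}

#' Read a TIFF written by [write_image_tiff()]
#'
#' @param file path to the TIFF.
#' @return Numeric array in original integer units, with metadata restored
#'   from the YAML sidecar when present.
#' @export
read_image_tiff <- function(file) {
  px <- tiff::readTIFF(file)
  meta_file <- paste0(file, ".yaml")
  bit_depth <- 8L
  meta <- NULL
  if (file.exists(meta_file)) {
    meta <- yaml::read_yaml(meta_file)
    bit_depth <- meta$bit_depth %||% 8L
  }
  out <- round(px * (2^bit_depth - 1))
  if (!is.null(meta)) {
    attr(out, "bit_depth") <- bit_depth
    attr(out, "pixel_size_um") <- meta$pixel_size_um
    attr(out, "tile_origin_um") <- meta$tile_origin_um
    attr(out, "face_z_um") <- meta$face_z_um
    attr(out, "section_index") <- meta$section_index
  }
  out
}
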