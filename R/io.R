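# Image IO on the package's canonical scale: everything internal is a [0,1]
# double matrix (or HxWx3 array); files are 8- or 16-bit PNG/TIFF.

#' Read a PNG or TIFF image onto the canonical [0, 1] scale
#'
#' Grayscale images come back as an HxW matrix, RGB(A) as an HxWx3 array
#' (alpha dropped). The source bit depth is recorded in attribute
#' `bit_depth` for symmetric write-back.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix or HxWx3 array in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    info <- attr(png::readPNG(path, info = TRUE), "info")
    img <- png::readPNG(path)
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
    attributes(img) <- list(dim = dim(img))
  } else {
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)",
                 ext), call. = FALSE)
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) img <- img[, , 1:3] else img <- img[, , 1]
  }
  attr(img, "bit_depth") <- as.integer(depth)
  img
}

#' Write an image from the canonical [0, 1] scale
#'
#' Quantizes with round-half-up to the target bit depth and writes PNG or
#' TIFF by extension. Out-of-range input is an error: mapping fused
#' intensities back into [0, 1] is the fusion stage's responsibility.
#'
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param img matrix or HxWx3 array in [0, 1].
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, img, bit_depth = 8L) {
  if (min(img) < 0 || max(img) > 1) {
    stop("`img` must be within [0, 1] before writing", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16",
                                       call. = FALSE)
  levels <- 2^bit_depth - 1
  q <- floor(img * levels + 0.5) / levels   # round half up
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth == 16L) {
      stop("16-bit output is TIFF-only (PNG writing is 8-bit)",
           call. = FALSE)
    }
    png::writePNG(q, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, where = path, bits.per.sample = bit_depth)
  } else {
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Affinely rescale a component to [0, 1] for display
#'
#' Saliency and noise components are signed; this maps their range onto
#' [0, 1] (a constant component maps to 0.5).
#' @param x numeric matrix.
#' @return matrix in [0, 1].
#' @export
rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(matrix(0.5, nrow(x), ncol(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}
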