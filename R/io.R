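# Image I/O: PNG, TIFF and 2-D NIfTI slices in and out, always through the
# internal [0,1] grayscale matrix representation.

img_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.png$", low)) "png"
  else if (grepl("\\.tiff?$", low)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else stop_pyrfuse(sprintf("cannot read '%s': unknown format (expected .png, .tif(f), .nii(.gz))", path),
                    "pyrfuse_io_error")
}

#' Read a grayscale image
#'
#' Reads PNG, TIFF or a NIfTI slice and returns a numeric matrix normalized
#' to \eqn{[0,1]}.  Multi-channel (RGB/RGBA) inputs are converted to
#' luminance (Rec. 601 weights) with a message; 3-D NIfTI volumes yield
#' their first slice.  PNG/TIFF values arrive already scaled to \eqn{[0,1]}
#' by their bit depth; NIfTI intensities are rescaled by their observed
#' range.
#'
#' @param path File path.
#' @param verbose Log conversions to stderr (default TRUE).
#' @return Numeric matrix in \eqn{[0,1]}.
#' @export
read_gray_image <- function(path, verbose = TRUE) {
  if (!file.exists(path))
    stop_pyrfuse(sprintf("cannot read '%s': file does not exist", path),
                 "pyrfuse_io_error")
  fmt <- img_format(path)
  x <- switch(fmt,
              png = png::readPNG(path),
              tiff = tiff::readTIFF(path),
              nifti = {
                v <- RNifti::readNifti(path)
                arr <- as.array(v)
                if (length(dim(arr)) > 2L) {
                  if (verbose) message(sprintf("'%s': taking first slice of %s volume",
                                               path, paste(dim(arr), collapse = "x")))
                  arr <- arr[, , 1L]
                }
                rng <- range(arr)
                if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1]) else arr * 0
              })
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    if (verbose) message(sprintf("'%s': converting %d-channel image to luminance",
                                 path, nc))
    x <- if (nc >= 3L)
      0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    else x[, , 1L]
  }
  clip01(matrix(as.numeric(x), nrow(x), ncol(x)))
}

#' Write a grayscale image
#'
#' Writes a \eqn{[0,1]} matrix as PNG (8-bit), TIFF (16-bit) or NIfTI,
#' chosen by the file extension.
#'
#' @param img Numeric matrix; values are clipped to \eqn{[0,1]}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gray_image <- function(img, path) {
  check_gray(img)
  img <- clip01(img)
  switch(img_format(path),
         png = png::writePNG(img, path),
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
         nifti = RNifti::writeNifti(RNifti::asNifti(img), path))
  invisible(path)
}
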