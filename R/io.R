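#' Read a multi-page TIFF stack
#'
#' Reads an 8- or 16-bit grayscale multi-page TIFF into a [frame_stack()].
#' RGB pages are converted to luminance with a warning; pages of mixed bit
#' depth are rejected.
#'
#' @param path path to a TIFF file.
#' @param fps optional acquisition rate stored on the stack.
#' @return a [frame_stack()]. Intensities are scaled to `[0, 1]`.
#' @export
read_stack <- function(path, fps = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) NA_integer_ else as.integer(b[1])
  }, integer(1))
  if (length(unique(bits[!is.na(bits)])) > 1)
    stop("mixed bit-depth pages in ", path, ": ", paste(bits, collapse = ", "))
  mats <- vector("list", length(pages))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) {
      warning("page ", k, " is RGB; converting to luminance")
      p <- 0.2126 * p[, , 1] + 0.7152 * p[, , 2] + 0.0722 * p[, , 3]
    }
    if (!is.matrix(p)) stop("corrupt page ", k, " in ", path)
    if (k > 1 && !identical(dim(p), dim(mats[[1]])))
      stop("page ", k, " has different dimensions")
    mats[[k]] <- p
  }
  frames <- array(unlist(mats, use.names = FALSE),
                  dim = c(dim(mats[[1]]), length(mats)))
  frame_stack(frames, fps = fps)
}

#' Write a frame stack as a multi-page TIFF
#'
#' Frames are quantized to the requested bit depth. A write/read round trip
#' is bit-identical for data already on the quantization grid.
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @param bits bits per sample, 8 or 16 (default).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  mats <- lapply(seq_len(n_frames(stack)), function(t)
    pmin(pmax(stack$frames[, , t], 0), 1))
  tiff::writeTIFF(mats, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write a projection image to TIFF or PNG
#'
#' @param image a [project()] result or a plain matrix.
#' @param path output path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @param bits bits per sample for TIFF output.
#' @return `path`, invisibly.
#' @export
write_projection <- function(image, path, bits = 16L) {
  m <- if (inherits(image, "projection_image")) image$image else image
  m <- pmin(pmax(m, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("png package required for PNG output")
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}
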