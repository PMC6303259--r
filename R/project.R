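#' Z-project a stack: minima or average image
#'
#' The two projections are the heart of label-free tracer angiography. With
#' dark erythrocytes on a bright field, the per-pixel **minima** over a long
#' registered stack keeps, at every pixel, the darkest tracer that ever
#' passed — rendering the full lumen of every perfused vessel (an
#' angiogram without contrast agent). The per-pixel **average** is
#' proportional to mean tracer occupancy, a qualitative map of flow.
#' Pixels marked invalid by registration are excluded; a pixel with no valid
#' contribution is filled with the median of the projected image.
#'
#' @param stack a [frame_stack()] (>= 1 frame).
#' @param mode `"minima"` or `"average"`.
#' @return an object of class `projection_image`: list with `image`
#'   (`H x W` matrix), `mode`, `n` (contributing frames) and `count_map`
#'   (per-pixel count of valid contributions).
#' @export
project <- function(stack, mode = c("minima", "average")) {
  mode <- match.arg(mode)
  n <- n_frames(stack)
  if (n < 1) stop("empty stack")
  fr <- stack$frames
  if (is.null(stack$valid)) {
    count <- matrix(n, dim(fr)[1], dim(fr)[2])
    img <- if (mode == "minima") apply(fr, c(1, 2), min)
           else apply(fr, c(1, 2), mean)
  } else {
    v <- stack$valid
    count <- apply(v, c(1, 2), sum)
    if (mode == "minima") {
      tmp <- fr
      tmp[!v] <- Inf
      img <- apply(tmp, c(1, 2), min)
      img[!is.finite(img)] <- NA
    } else {
      tmp <- fr
      tmp[!v] <- 0
      img <- apply(tmp, c(1, 2), sum) / pmax(count, 1)
      img[count == 0] <- NA
    }
    if (anyNA(img)) img[is.na(img)] <- median(img, na.rm = TRUE)
  }
  structure(list(image = img, mode = mode, n = n, count_map = count),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %s of %d frame(s), %d x %d px, range [%.3f, %.3f]\n",
              x$mode, x$n, nrow(x$image), ncol(x$image),
              min(x$image), max(x$image)))
  invisible(x)
}

#' Remove slowly varying illumination
#'
#' Estimates the background as the grayscale morphological closing of the
#' image with a disc much larger than any vessel (the upper envelope of the
#' bright field: dark features narrower than the disc are erased, smooth
#' illumination is followed exactly) and subtracts it, re-centering on the
#' background mean. The equivalent of rolling-ball background subtraction
#' for dark-on-bright imagery.
#'
#' @param image a `projection_image` or a plain matrix.
#' @param radius background scale in px; must be much larger than the vessel
#'   width.
#' @param vessel_width optional known vessel width; a warning is issued when
#'   `radius <= vessel_width`, since vessels themselves would be flattened
#'   away.
#' @return same type as the input, background-flattened.
#' @export
flatten_background <- function(image, radius, vessel_width = NULL) {
  stopifnot(radius >= 1)
  if (!is.null(vessel_width) && radius <= vessel_width)
    warning("radius <= vessel width: vessels would be erased by flattening")
  m <- if (inherits(image, "projection_image")) image$image else image
  brush <- EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
  bg <- as.matrix(EBImage::closing(m, brush))
  out <- m - bg + mean(bg)
  if (inherits(image, "projection_image")) {
    image$image <- out
    image
  } else out
}

#' Otsu vessel mask from a minima image
#'
#' Thresholds a minima projection with Otsu's criterion; vessels are the
#' below-threshold (dark) phase.
#'
#' @param image a `projection_image` or matrix.
#' @return logical matrix, `TRUE` inside vessels; threshold attached as
#'   attribute `"threshold"`.
#' @export
otsu_mask <- function(image) {
  m <- if (inherits(image, "projection_image")) image$image else image
  rng <- range(m)
  thr <- EBImage::otsu(EBImage::Image(m), range = rng)
  out <- m < thr
  attr(out, "threshold") <- thr
  out
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical matrices of identical size.
#' @return Dice coefficient `2|A∩B| / (|A| + |B|)`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
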