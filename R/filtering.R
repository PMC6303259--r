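#' Discard defocused frames by sharpness ranking
#'
#' Two sharpness criteria are available. `"roi"` is the operator-driven
#' criterion of transmission imaging practice: a small region of interest is
#' placed over a crisp dark feature, and frames are ranked by the mean gray
#' level inside it — defocus diffuses light into the dark feature, so darker
#' means sharper. `"gradient"` is the automatic alternative for headless and
#' time-lapse runs: frames are ranked by mean squared intensity gradient
#' (higher means sharper), over the ROI if one is given, else the whole
#' frame. The sharpest `keep_fraction` of frames is retained; relative frame
#' order is preserved.
#'
#' @param stack a [frame_stack()].
#' @param roi region of interest `c(x, y, w, h)` (1-based corner, width,
#'   height), required for `method = "roi"`.
#' @param keep_fraction fraction of frames to keep, in `(0, 1]`; the number
#'   kept is `ceiling(keep_fraction * n)`. Default 0.5: with an oscillating
#'   preparation roughly one frame in two is in focus.
#' @param method sharpness criterion; defaults to `"roi"` when `roi` is
#'   given, `"gradient"` otherwise.
#' @return the filtered [frame_stack()]; ranking scores are attached as
#'   attribute `"scores"`.
#' @export
filter_blurred <- function(stack, roi = NULL, keep_fraction = 0.5,
                           method = c("auto", "roi", "gradient")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (is.null(roi)) "gradient" else "roi"
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  n <- n_frames(stack)
  d <- dim(stack$frames)
  crop <- function(m) m
  if (!is.null(roi)) {
    roi <- round(roi)
    if (roi[3] < 1 || roi[4] < 1) stop("roi has zero area")
    x0 <- roi[1]; y0 <- roi[2]
    x1 <- x0 + roi[3] - 1; y1 <- y0 + roi[4] - 1
    if (x0 < 1 || y0 < 1 || x1 > d[2] || y1 > d[1])
      stop("roi extends outside the frame")
    crop <- function(m) m[y0:y1, x0:x1, drop = FALSE]
  } else if (method == "roi") {
    stop("method 'roi' requires a roi")
  }
  score <- vapply(seq_len(n), function(t) {
    m <- crop(stack$frames[, , t])
    if (method == "roi") {
      -mean(m)                               # darker dark feature = sharper
    } else {
      gx <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
      gy <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
      mean(gx^2) + mean(gy^2)
    }
  }, numeric(1))
  nkeep <- ceiling(keep_fraction * n)
  keep <- sort(order(score, decreasing = TRUE)[seq_len(nkeep)])
  out <- stack_subset(stack, keep)
  attr(out, "scores") <- score
  out
}

#' Discard aberrant frames by correlation with a reference
#'
#' Removes frames that are too different from a chosen reference frame
#' (spurious saturated frames occasionally produced by camera electronics, or
#' gross tissue displacements). Dissimilarity is measured by normalized
#' cross-correlation with the reference; frames below the threshold are
#' dropped. The reference frame is always kept.
#'
#' @param stack a [frame_stack()].
#' @param reference_slot slot index of the reference frame (default: middle
#'   slot).
#' @param max_distance correlation threshold in `[-1, 1]`: frames whose NCC
#'   with the reference falls below it are removed. `-1` accepts everything.
#' @return the filtered [frame_stack()]; correlations are attached as
#'   attribute `"ncc"`.
#' @export
discard_aberrant <- function(stack, reference_slot = NULL, max_distance = 0.2) {
  n <- n_frames(stack)
  if (is.null(reference_slot)) reference_slot <- (n + 1) %/% 2
  stopifnot(reference_slot >= 1, reference_slot <= n)
  ref <- as.vector(stack_frame(stack, reference_slot))
  ncc <- vapply(seq_len(n), function(t) {
    v <- as.vector(stack$frames[, , t])
    if (sd(v) < 1e-12 || sd(ref) < 1e-12) return(ifelse(identical(v, ref), 1, 0))
    cor(v, ref)
  }, numeric(1))
  keep <- which(ncc >= max_distance | seq_len(n) == reference_slot)
  if (length(keep) == 1 && n > 1)
    warning("threshold removed all frames but the reference")
  out <- stack_subset(stack, keep)
  attr(out, "ncc") <- ncc
  out
}
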