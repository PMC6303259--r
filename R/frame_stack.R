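#' Construct a frame stack
#'
#' A frame stack is an ordered grayscale image sequence stored as an
#' `H x W x T` numeric array with intensities in `[0, 1]`, together with the
#' original acquisition index of each slot. Acquisition indices make every
#' later reordering (decorrelation shuffle) and discard (blur or aberrant
#' frame rejection) invertible: [unshuffle()] restores acquisition order at
#' any point.
#'
#' @param frames numeric `H x W x T` array (a single matrix is promoted to
#'   `T = 1`), values expected in `[0, 1]`.
#' @param acq_index integer vector of length `T`: original acquisition index
#'   (1-based) of each slot. Defaults to `1:T`.
#' @param fps acquisition frame rate in Hz, if known.
#' @param valid optional logical array of the same shape marking pixels that
#'   carry data (used after registration to exclude resampled-in borders from
#'   projections). Default: all valid.
#' @return an object of class `frame_stack`.
#' @seealso [read_stack()], [project()]
#' @export
frame_stack <- function(frames, acq_index = NULL, fps = NA_real_, valid = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  nt <- dim(frames)[3]
  if (is.null(acq_index)) acq_index <- seq_len(nt)
  acq_index <- as.integer(acq_index)
  if (length(acq_index) != nt) stop("acq_index must have one entry per frame")
  if (anyDuplicated(acq_index)) stop("acq_index must be unique")
  if (!is.null(valid)) stopifnot(identical(dim(valid), dim(frames)))
  structure(list(frames = frames, acq_index = acq_index, fps = fps,
                 valid = valid),
            class = "frame_stack")
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px", d[3], d[1], d[2]))
  if (!is.na(x$fps)) cat(sprintf(", %g fps", x$fps))
  rng <- range(x$acq_index)
  cat(sprintf("; acquisition indices %d..%d\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

# Keep a subset of slots (in the given slot order), carrying metadata along.
stack_subset <- function(stack, slots) {
  frame_stack(stack$frames[, , slots, drop = FALSE],
              acq_index = stack$acq_index[slots], fps = stack$fps,
              valid = if (!is.null(stack$valid)) stack$valid[, , slots, drop = FALSE])
}

# Single frame as a matrix.
stack_frame <- function(stack, slot) stack$frames[, , slot]
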