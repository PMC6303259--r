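#' Decorrelation shuffle permutation
#'
#' Builds the interleaving permutation used to decorrelate tracer motion
#' before registration: output slots alternate between the first and second
#' half of the acquisition, `1, H+1, 2, H+2, ...` with `H = ceiling(N / 2)`,
#' so every pair of adjacent output frames is at least `H - 1 >=
#' floor(N / 2) - 2` acquisition steps apart. Consecutive frames of the
#' shuffled stack therefore show essentially independent tracer
#' configurations, and registration cannot lock onto the coherent
#' erythrocyte flow. For odd `N` the first half is the larger one.
#'
#' @param n number of frames (>= 4).
#' @return an object of class `shuffle_permutation` with `forward` (slot ->
#'   acquisition index) and `inverse` maps.
#' @export
shuffle_permutation <- function(n) {
  if (n < 4) stop("need at least 4 frames to shuffle")
  H <- ceiling(n / 2)
  fwd <- integer(n)
  fwd[seq(1, n, by = 2)] <- seq_len(H)
  if (n > 1) fwd[seq(2, n, by = 2)] <- H + seq_len(n - H)
  inv <- integer(n)
  inv[fwd] <- seq_len(n)
  structure(list(forward = fwd, inverse = inv, n = n),
            class = "shuffle_permutation")
}

#' @export
print.shuffle_permutation <- function(x, ...) {
  sep <- abs(diff(x$forward))
  cat(sprintf("<shuffle_permutation> n = %d, min adjacent separation = %d\n",
              x$n, min(sep)))
  invisible(x)
}

#' Shuffle a stack to decorrelate tracer motion
#'
#' Reorders the frames by the interleaving permutation of
#' [shuffle_permutation()]. The permutation is returned (and recorded in the
#' stack's acquisition indices) so [unshuffle()] can restore acquisition
#' order at any later stage, even after frames have been discarded.
#'
#' @param stack a [frame_stack()] in acquisition order (>= 4 frames).
#' @return list with `stack` (shuffled) and `permutation`.
#' @export
shuffle_decorrelate <- function(stack) {
  perm <- shuffle_permutation(n_frames(stack))
  list(stack = stack_subset(stack, perm$forward), permutation = perm)
}

#' Restore acquisition order
#'
#' Reorders frames by increasing acquisition index. Frames discarded since
#' the shuffle are simply skipped: the output is in strictly increasing
#' acquisition order.
#'
#' @param stack a [frame_stack()].
#' @param permutation optional [shuffle_permutation()]; when given, the
#'   stack's acquisition indices are checked against its domain.
#' @return a [frame_stack()] in acquisition order.
#' @export
unshuffle <- function(stack, permutation = NULL) {
  if (!is.null(permutation)) {
    if (!all(stack$acq_index %in% seq_len(permutation$n)))
      stop("stack acquisition indices do not match the permutation domain")
  }
  stack_subset(stack, order(stack$acq_index))
}
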