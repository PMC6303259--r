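#' Ensemble block-matching PIV over a stack
#'
#' Estimates a displacement field from an acquisition-ordered (registered,
#' unshuffled) stack by interrogation-window cross-correlation: for every
#' window position, the cross-covariance surfaces of all frame pairs
#' `(t, t + frame_step)` are accumulated (ensemble correlation — robust for
#' sparse tracers in steady flow), and the displacement is the surface peak
#' refined to subpixel precision by a parabolic fit. Vector quality is the
#' ratio of the primary correlation peak to the second-highest peak outside
#' its immediate neighborhood; low-quality vectors are meant to be flagged
#' with [median_filter_vectors()], not silently dropped.
#'
#' @param stack a [frame_stack()] in acquisition order, >= 2 frames.
#' @param window_px interrogation window side, px (>= 8).
#' @param overlap window overlap fraction in `[0, 0.75]`.
#' @param frame_step frame separation of correlated pairs (>= 1).
#' @return a `velocity_field`: data.frame with window centers `x`, `y`,
#'   displacements `u`, `v` in px/frame, `quality`, `valid`; grid geometry in
#'   attributes.
#' @export
piv_pass <- function(stack, window_px = 16, overlap = 0.5, frame_step = 1) {
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; nt <- d[3]
  if (window_px > min(H, W)) stop("interrogation window larger than the image")
  stopifnot(window_px >= 8, overlap >= 0, overlap <= 0.75, frame_step >= 1,
            nt > frame_step)
  wp <- as.integer(window_px)
  spacing <- max(1L, as.integer(round(wp * (1 - overlap))))
  x0s <- seq(1L, W - wp + 1L, by = spacing)
  y0s <- seq(1L, H - wp + 1L, by = spacing)
  pairs <- seq_len(nt - frame_step)
  res <- expand.grid(yi = seq_along(y0s), xi = seq_along(x0s))
  out <- data.frame(x = numeric(nrow(res)), y = numeric(nrow(res)),
                    u = NA_real_, v = NA_real_, quality = NA_real_,
                    valid = TRUE)
  np <- 2L * wp                         # zero-padded (linear) correlation
  lag <- c(0:(np %/% 2 - 1), -(np %/% 2):-1)   # lag of each surface index
  # unbiased normalization: number of overlapping pixels at each lag
  ovl <- pmax(wp - abs(lag), 0)
  ovl2 <- ovl %o% ovl
  searchable <- abs(lag) <= wp %/% 2 - 1
  search_mask <- searchable %o% searchable
  for (k in seq_len(nrow(res))) {
    x0 <- x0s[res$xi[k]]; y0 <- y0s[res$yi[k]]
    acc <- matrix(0, np, np)
    Ap <- Bp <- matrix(0, np, np)
    for (t in pairs) {
      A <- stack$frames[y0:(y0 + wp - 1), x0:(x0 + wp - 1), t]
      B <- stack$frames[y0:(y0 + wp - 1), x0:(x0 + wp - 1), t + frame_step]
      Ap[seq_len(wp), seq_len(wp)] <- A - mean(A)
      Bp[seq_len(wp), seq_len(wp)] <- B - mean(B)
      acc <- acc + Re(fft(fft(Bp) * Conj(fft(Ap)), inverse = TRUE))
    }
    norm <- acc / pmax(ovl2, 1)
    norm[!search_mask] <- -Inf
    pk <- which.max(norm)
    py <- (pk - 1) %% np + 1
    px <- (pk - 1) %/% np + 1
    cyc <- function(i) (i - 1) %% np + 1
    subfit <- function(vm1, v0, vp1) {
      den <- vm1 - 2 * v0 + vp1
      if (!is.finite(den) || abs(den) < 1e-12) 0
      else max(min(0.5 * (vm1 - vp1) / den, 0.5), -0.5)
    }
    ddy <- subfit(norm[cyc(py - 1), px], norm[py, px], norm[cyc(py + 1), px])
    ddx <- subfit(norm[py, cyc(px - 1)], norm[py, px], norm[py, cyc(px + 1)])
    masked <- norm
    for (oy in -1:1) for (ox in -1:1) masked[cyc(py + oy), cyc(px + ox)] <- -Inf
    second <- max(masked)
    out$x[k] <- x0 + (wp - 1) / 2
    out$y[k] <- y0 + (wp - 1) / 2
    out$u[k] <- (lag[px] + ddx) / frame_step
    out$v[k] <- (lag[py] + ddy) / frame_step
    out$quality[k] <- if (is.finite(second) && second > 0) norm[py, px] / second
                      else Inf
  }
  structure(out, class = c("velocity_field", "data.frame"),
            window_px = wp, overlap = overlap, spacing = spacing,
            frame_step = frame_step)
}

#' Flag outlier vectors by the normalized local median test
#'
#' Compares every vector with the median of its grid neighbors; vectors
#' whose residual exceeds `threshold` times the local median residual (plus
#' a small noise floor) are flagged invalid, not removed.
#'
#' @param field a [piv_pass()] result.
#' @param threshold residual threshold in local median absolute deviations.
#' @param eps noise floor on the residuals, px/frame.
#' @return the field with its `valid` column updated.
#' @export
median_filter_vectors <- function(field, threshold = 3, eps = 0.1) {
  stopifnot(nrow(field) > 0)
  sp <- attr(field, "spacing")
  for (k in seq_len(nrow(field))) {
    nb <- which(abs(field$x - field$x[k]) <= 1.5 * sp &
                abs(field$y - field$y[k]) <= 1.5 * sp)
    nb <- setdiff(nb, k)
    if (length(nb) < 3) next
    mu <- median(field$u[nb]); mv <- median(field$v[nb])
    rnb <- sqrt((field$u[nb] - mu)^2 + (field$v[nb] - mv)^2)
    r0 <- median(rnb)
    rk <- sqrt((field$u[k] - mu)^2 + (field$v[k] - mv)^2)
    if (rk / (r0 + eps) > threshold) field$valid[k] <- FALSE
  }
  field
}

#' Write a velocity field as CSV
#'
#' @param field a [piv_pass()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(field, path) {
  write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}
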