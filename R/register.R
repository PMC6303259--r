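# --- shared image resampling utilities ------------------------------------

# Sample m at (x - dx, y - dy) with bilinear interpolation: displaces the
# content by (+dx, +dy). Out-of-frame source pixels get `fill`.
.bilinear_shift_matrix <- function(m, dx, dy, fill = 0) {
  .resample_rigid(m, dx, dy, 0, fill = fill)$image
}

# Rigid resampling about the image center. With inverse = FALSE the content
# is displaced by (dx, dy) and rotated by theta (radians); with
# inverse = TRUE the transform is undone (used to align an observed frame).
# Returns the image and the validity mask of in-frame source pixels.
.resample_rigid <- function(m, dx, dy, theta = 0, fill = 0, inverse = FALSE) {
  H <- nrow(m); W <- ncol(m)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  if (inverse) {
    u <- X - cx + dx; v <- Y - cy + dy
    sx <- cos(theta) * u - sin(theta) * v + cx
    sy <- sin(theta) * u + cos(theta) * v + cy
  } else {
    u <- X - cx; v <- Y - cy
    sx <- cos(theta) * u + sin(theta) * v + cx - dx
    sy <- -sin(theta) * u + cos(theta) * v + cy - dy
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  valid <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  x0c <- pmin(pmax(x0, 1), W); x1c <- pmin(x0c + 1, W)
  y0c <- pmin(pmax(y0, 1), H); y1c <- pmin(y0c + 1, H)
  g <- function(xi, yi) m[cbind(as.vector(yi), as.vector(xi))]
  out <- (1 - fx) * (1 - fy) * g(x0c, y0c) + fx * (1 - fy) * g(x1c, y0c) +
    (1 - fx) * fy * g(x0c, y1c) + fx * fy * g(x1c, y1c)
  out <- matrix(out, H, W)
  out[!valid] <- fill
  list(image = out, valid = valid)
}

# Gaussian blur with replicated borders (defocus emulation, sharpness tests).
.gauss_blur <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}

# --- translation estimation by windowed FFT correlation --------------------

#' Subpixel translation estimate by FFT correlation
#'
#' Estimates the displacement `(dx, dy)` such that `b` is `a` displaced by
#' that amount. Both images are Hann-windowed and correlated through the
#' FFT; the integer peak of the correlation surface is then refined by
#' evaluating the band-limited surface on a 1/`upsample` px grid around the
#' peak with a local matrix DFT, which avoids the bias of a parabolic
#' three-point fit.
#'
#' Two spectral normalizations are offered. `"cross"` (default) is plain
#' cross-correlation: it weights spectral components by their energy, which
#' keeps the estimate anchored to the static scene when part of the field is
#' moving tracer texture. `"phase"` whitens the spectrum (classic phase
#' correlation): a sharper peak on rigidly moving, feature-rich scenes, but
#' it weights all frequencies equally and so can lock onto coherently
#' flowing tracers.
#'
#' @param a,b numeric matrices of identical size.
#' @param window apply a Hann window (default `TRUE`).
#' @param normalize `"cross"` or `"phase"`.
#' @param upsample subpixel refinement factor (default 20, i.e. 0.05 px
#'   grid).
#' @return list with `dx`, `dy` and `peak`, a normalized correlation score
#'   in `[0, 1]`.
#' @export
phase_correlation <- function(a, b, window = TRUE,
                              normalize = c("cross", "phase"), upsample = 20) {
  normalize <- match.arg(normalize)
  stopifnot(identical(dim(a), dim(b)))
  H <- nrow(a); W <- ncol(a)
  a <- a - mean(a); b <- b - mean(b)
  if (window) {
    wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(H) - 1) / (H - 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(W) - 1) / (W - 1))
    win <- wy %o% wx
    a <- a * win; b <- b * win
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(list(dx = 0, dy = 0, peak = 0))
  R <- fft(b) * Conj(fft(a))
  if (normalize == "phase") R <- R / (Mod(R) + 1e-12)
  r <- Re(fft(R, inverse = TRUE)) / length(R)
  pk <- which.max(r)
  py <- (pk - 1) %% H + 1
  px <- (pk - 1) %/% H + 1
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  x0 <- wrap(px, W); y0 <- wrap(py, H)
  peak <- r[py, px]
  if (upsample > 1) {
    kx <- c(0:(W %/% 2), -((ceiling(W / 2) - 1):1))
    ky <- c(0:(H %/% 2), -((ceiling(H / 2) - 1):1))
    us <- seq(-1.2, 1.2, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(y0 + us, ky) / H)
    Ex <- exp(2i * pi * outer(kx, x0 + us) / W)
    rup <- Re(Ey %*% R %*% Ex) / length(R)
    best <- which(rup == max(rup), arr.ind = TRUE)[1, ]
    y0 <- y0 + us[best[1]]
    x0 <- x0 + us[best[2]]
    peak <- max(rup)
  }
  score <- if (normalize == "phase") peak else peak / (na * nb)
  list(dx = x0, dy = y0, peak = min(max(score, 0), 1))
}

# --- stack registration ----------------------------------------------------

#' Register a stack to a common frame
#'
#' Estimates a rigid transform (translation, optionally with a small
#' rotation) for every frame and resamples all frames into the reference
#' frame's coordinates with bilinear interpolation. Pixels resampled from
#' outside the frame are filled with the frame's median intensity and marked
#' invalid, so they are excluded from later projections (this is what keeps
#' dark borders from corrupting the minima image).
#'
#' With `reference = "fixed"` (default), estimation is iterative: frames are
#' first matched to the reference frame, then re-matched against the mean of
#' the aligned stack for `passes - 1` further passes. Averaging washes out
#' the moving erythrocytes, so the template presents only the static scene
#' and the tracer texture of an individual frame acts as uncorrelated noise
#' — the estimate cannot drift with the flow. Transforms are re-centered
#' after every pass so the reference frame keeps the identity transform.
#'
#' `reference = "previous"` instead matches each frame to its predecessor
#' and accumulates the transforms, emulating consecutive-frame plugin
#' registration. In that mode coherent tracer flow biases every pairwise
#' estimate the same way and the stack drifts — unless it was decorrelated
#' by [shuffle_decorrelate()] first, which is precisely why the shuffle
#' exists. `"previous"` supports the translation model only.
#'
#' @param stack a [frame_stack()] (>= 1 frame).
#' @param reference_slot reference frame slot (default: middle slot); its
#'   transform is the identity.
#' @param model `"translation"` (default) or `"rigid"` (adds a rotation
#'   search on the first pass).
#' @param reference `"fixed"` or `"previous"` (see Details).
#' @param passes number of estimation passes in `"fixed"` mode (>= 1;
#'   default 2).
#' @param theta_range_deg half-range of the rotation search, degrees.
#' @return list with `stack` (registered, with validity masks) and `result`,
#'   a data.frame with one row per frame: `slot`, `acq_index`, `dx`, `dy`,
#'   `theta`, `score` (correlation with the reference after alignment) and
#'   `low_confidence` (featureless frames, which fall back to the identity
#'   transform).
#' @export
register_stack <- function(stack, reference_slot = NULL,
                           model = c("translation", "rigid"),
                           reference = c("fixed", "previous"),
                           passes = 2, theta_range_deg = 3) {
  model <- match.arg(model)
  reference <- match.arg(reference)
  n <- n_frames(stack)
  if (is.null(reference_slot)) reference_slot <- (n + 1) %/% 2
  stopifnot(reference_slot >= 1, reference_slot <= n, passes >= 1)
  if (reference == "previous" && model == "rigid")
    stop("reference = 'previous' supports the translation model only")

  est_translation <- function(refm, m) {
    if (sd(m) < 1e-12 || sd(refm) < 1e-12)
      return(list(dx = 0, dy = 0, peak = 0, low = TRUE))
    p <- phase_correlation(refm, m)
    list(dx = p$dx, dy = p$dy, peak = p$peak, low = FALSE)
  }
  est_rigid <- function(refm, m) {
    if (sd(m) < 1e-12 || sd(refm) < 1e-12)
      return(list(dx = 0, dy = 0, theta = 0, peak = 0, low = TRUE))
    thetas <- seq(-theta_range_deg, theta_range_deg, by = 0.5) * pi / 180
    peaks <- numeric(length(thetas))
    for (k in seq_along(thetas)) {
      mu <- .resample_rigid(m, 0, 0, thetas[k], fill = median(m),
                            inverse = TRUE)$image
      peaks[k] <- phase_correlation(refm, mu, upsample = 1)$peak
    }
    k <- which.max(peaks)
    th <- thetas[k]
    if (k > 1 && k < length(thetas)) {   # parabolic refinement over angle
      den <- peaks[k - 1] - 2 * peaks[k] + peaks[k + 1]
      if (abs(den) > 1e-12)
        th <- th + 0.5 * (peaks[k - 1] - peaks[k + 1]) / den *
          (thetas[2] - thetas[1])
    }
    mu <- .resample_rigid(m, 0, 0, th, fill = median(m), inverse = TRUE)$image
    p <- phase_correlation(refm, mu)
    list(dx = p$dx, dy = p$dy, theta = th, peak = p$peak, low = FALSE)
  }

  dx <- dy <- th <- numeric(n); low <- logical(n)
  if (reference == "fixed") {
    refm <- stack_frame(stack, reference_slot)
    for (t in seq_len(n)) {
      if (t == reference_slot) next
      e <- if (model == "rigid") est_rigid(refm, stack_frame(stack, t))
           else est_translation(refm, stack_frame(stack, t))
      dx[t] <- e$dx; dy[t] <- e$dy; low[t] <- e$low
      if (model == "rigid") th[t] <- e$theta
    }
    if (passes > 1 && n > 2) {
      for (p in seq_len(passes - 1)) {
        acc <- matrix(0, dim(stack$frames)[1], dim(stack$frames)[2])
        for (t in seq_len(n)) {
          m <- stack_frame(stack, t)
          acc <- acc + .resample_rigid(m, dx[t], dy[t], th[t],
                                       fill = median(m), inverse = TRUE)$image
        }
        tmpl <- acc / n
        for (t in seq_len(n)) {
          if (low[t]) next
          m <- stack_frame(stack, t)
          if (model == "rigid" && th[t] != 0)
            m <- .resample_rigid(m, 0, 0, th[t], fill = median(m),
                                 inverse = TRUE)$image
          e <- est_translation(tmpl, m)
          dx[t] <- e$dx; dy[t] <- e$dy
        }
        dx <- dx - dx[reference_slot]; dy <- dy - dy[reference_slot]
      }
    }
  } else {
    pdx <- pdy <- numeric(n)            # pairwise slot t-1 -> t
    for (t in seq_len(n)[-1]) {
      e <- est_translation(stack_frame(stack, t - 1), stack_frame(stack, t))
      pdx[t] <- e$dx; pdy[t] <- e$dy; low[t] <- e$low
    }
    dx <- cumsum(pdx); dy <- cumsum(pdy)
    dx <- dx - dx[reference_slot]; dy <- dy - dy[reference_slot]
  }

  frames <- array(0, dim = dim(stack$frames))
  valid <- array(TRUE, dim = dim(stack$frames))
  prev_valid <- stack$valid
  for (t in seq_len(n)) {
    m <- stack_frame(stack, t)
    r <- .resample_rigid(m, dx[t], dy[t], th[t], fill = median(m),
                         inverse = TRUE)
    frames[, , t] <- r$image
    v <- r$valid
    if (!is.null(prev_valid))
      v <- v & .resample_rigid(prev_valid[, , t] * 1, dx[t], dy[t], th[t],
                               fill = 0, inverse = TRUE)$image > 0.999
    valid[, , t] <- v
  }
  refm <- frames[, , reference_slot]
  score <- vapply(seq_len(n), function(t) {
    v <- valid[, , t]
    if (sum(v) < 16 || sd(frames[, , t][v]) < 1e-12 || sd(refm[v]) < 1e-12)
      return(0)
    cor(frames[, , t][v], refm[v])
  }, numeric(1))
  out <- frame_stack(frames, acq_index = stack$acq_index, fps = stack$fps,
                     valid = valid)
  res <- data.frame(slot = seq_len(n), acq_index = stack$acq_index,
                    dx = dx, dy = dy, theta = th, score = score,
                    low_confidence = low)
  list(stack = out, result = res)
}
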