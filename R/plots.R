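#' Display a projection image
#'
#' @param x a `projection_image`.
#' @param ... passed to [graphics::image()].
#' @export
plot.projection_image <- function(x, ...) {
  m <- x$image
  image(t(m)[, nrow(m):1], col = gray.colors(256, 0, 1), asp = nrow(m) / ncol(m),
        axes = FALSE, main = paste(x$mode, "projection"), ...)
  invisible(x)
}

#' Plot a cross-section absorption profile
#'
#' @param x a `vessel_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vessel_profile <- function(x, ...) {
  plot(x$position, x$od, type = "l", xlab = "position (px)",
       ylab = "optical density", ...)
  if (!x$empty) abline(h = 0.5 * x$peak_od, lty = 3)
  invisible(x)
}

#' Plot the axial velocity field of a cross-section solve
#'
#' @param x an `axial_flow` solution.
#' @param ... passed to [graphics::image()].
#' @export
plot.axial_flow <- function(x, ...) {
  image(x$xs, x$ys, x$w, asp = 1, xlab = "x (m)", ylab = "y (m)",
        main = sprintf("axial velocity, dp/dz = %.4g Pa/m", x$dpdz), ...)
  invisible(x)
}

#' Quiver plot of a PIV velocity field
#'
#' @param x a `velocity_field`.
#' @param scale arrow length per px/frame of displacement.
#' @param ... passed to [graphics::plot()].
#' @export
plot.velocity_field <- function(x, scale = 4, ...) {
  plot(x$x, max(x$y) - x$y + min(x$y), type = "n", xlab = "x (px)",
       ylab = "y (px)", asp = 1, ...)
  ok <- x$valid & sqrt(x$u^2 + x$v^2) > 1e-6
  yy <- max(x$y) - x$y + min(x$y)
  arrows(x$x[ok], yy[ok], x$x[ok] + scale * x$u[ok], yy[ok] - scale * x$v[ok],
         length = 0.04)
  invisible(x)
}

#' Plot the potential or flux magnitude of a lattice scenario
#'
#' @param x a `potential_field`.
#' @param what `"potential"` or `"flux"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.potential_field <- function(x, what = c("potential", "flux"), ...) {
  what <- match.arg(what)
  m <- if (what == "potential") x$V else compute_flux(x)$magnitude
  image(seq_len(nrow(m)), seq_len(ncol(m)), m, xlab = "row", ylab = "column",
        main = what, ...)
  invisible(x)
}
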