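#' Define a vessel segment
#'
#' Segments are the building blocks of a [vessel_network()]: a centerline
#' polyline with a lumen radius, a flattening factor and a mean erythrocyte
#' speed. Flattening follows the constant-perimeter circle-to-stadium family:
#' at flattening `f` the lumen of diameter `D = 2 * radius` has narrow-axis
#' gap `h = D * (1 - 0.75 * f)` (so `f = 1` gives the fully flattened gap
#' `D / 4`) and rendered width `pi * (D - h) / 2 + h` (1.43 `D` at `f = 1`).
#' Tracer speed is scaled by `1 - 0.8 * f`, so flattened tips carry visibly
#' less flux.
#'
#' @param from,to segment endpoints `c(x, y)` in pixel coordinates; ignored
#'   when `path` is given.
#' @param path optional `n x 2` matrix of polyline vertices `(x, y)`.
#' @param radius lumen radius in px (`> 0`).
#' @param flattening flattening factor in `[0, 1]`; 0 = cylindrical,
#'   1 = fully flattened.
#' @param speed mean tracer speed in px/frame for a cylindrical segment.
#' @return a `vessel_segment` list.
#' @export
vessel_segment <- function(from = NULL, to = NULL, path = NULL, radius = 5,
                           flattening = 0, speed = 1.5) {
  if (is.null(path)) path <- rbind(from, to)
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2)
  if (radius <= 0) stop("degenerate segment: radius must be > 0")
  if (flattening < 0 || flattening > 1) stop("flattening must be in [0, 1]")
  el <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2))
  if (any(el <= 0) || sum(el) <= 0) stop("degenerate segment: zero length")
  if (.polyline_self_intersects(path)) stop("polyline is self-intersecting")
  D <- 2 * radius
  h <- D * (1 - 0.75 * flattening)
  width <- pi * (D - h) / 2 + h
  structure(list(path = path, radius = radius, flattening = flattening,
                 speed = speed, length = sum(el), cumlen = c(0, cumsum(el)),
                 gap = h, width = width),
            class = "vessel_segment")
}

# Edge-pair crossing test, skipping adjacent edges.
.polyline_self_intersects <- function(p) {
  n <- nrow(p) - 1
  if (n < 3) return(FALSE)
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in 1:(n - 2)) for (j in (i + 2):n) {
    a <- p[i, ]; b <- p[i + 1, ]; c <- p[j, ]; d <- p[j + 1, ]
    if (sign(cross(a, b, c)) != sign(cross(a, b, d)) &&
        sign(cross(c, d, a)) != sign(cross(c, d, b))) return(TRUE)
  }
  FALSE
}

#' Assemble a vessel network
#'
#' Collects [vessel_segment()]s into a network, derives node connectivity
#' from shared endpoints and checks that every rendered lumen fits inside the
#' frame with a margin.
#'
#' @param segments list of [vessel_segment()]s.
#' @param width,height frame size in px.
#' @param margin minimum clearance between any rendered lumen edge and the
#'   frame border, in px.
#' @return an object of class `vessel_network` with elements `segments`,
#'   `nodes` (endpoint coordinates) and `segment_nodes` (node ids of each
#'   segment's ends).
#' @export
vessel_network <- function(segments, width, height, margin = 2) {
  if (inherits(segments, "vessel_segment")) segments <- list(segments)
  if (length(segments) == 0) stop("at least one segment required")
  stopifnot(width > 0, height > 0)
  for (s in segments) {
    hw <- s$width / 2
    xs <- s$path[, 1]; ys <- s$path[, 2]
    if (any(xs - hw < margin) || any(xs + hw > width - margin) ||
        any(ys - hw < margin) || any(ys + hw > height - margin))
      stop("segment does not fit inside the frame with margin ", margin)
  }
  ends <- do.call(rbind, lapply(segments, function(s)
    rbind(s$path[1, ], s$path[nrow(s$path), ])))
  nodes <- ends[!duplicated(round(ends, 1)), , drop = FALSE]
  node_id <- function(p) which(sqrt((nodes[, 1] - p[1])^2 + (nodes[, 2] - p[2])^2) < 0.5)[1]
  seg_nodes <- t(vapply(segments, function(s)
    c(node_id(s$path[1, ]), node_id(s$path[nrow(s$path), ])), numeric(2)))
  structure(list(segments = segments, width = width, height = height,
                 nodes = nodes, segment_nodes = seg_nodes),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d segment(s), %d node(s), frame %d x %d px\n",
              length(x$segments), nrow(x$nodes), x$width, x$height))
  invisible(x)
}

#' Seeded random vessel tree
#'
#' Convenience generator: a branching tree grown from the left edge by
#' recursive bifurcation, fully determined by `seed`.
#'
#' @param seed integer seed; identical seeds give identical networks.
#' @param width,height frame size in px.
#' @param depth number of bifurcation levels.
#' @param radius root lumen radius in px; children shrink by 0.75 per level.
#' @return a [vessel_network()].
#' @export
vessel_network_tree <- function(seed, width = 200, height = 160, depth = 2,
                                radius = 6) {
  with_seed(seed, {
    segs <- list()
    grow <- function(p0, angle, len, r, level) {
      p1 <- p0 + len * c(cos(angle), sin(angle))
      p1[1] <- min(max(p1[1], r * 2.6), width - r * 2.6)
      p1[2] <- min(max(p1[2], r * 2.6), height - r * 2.6)
      segs[[length(segs) + 1]] <<- vessel_segment(p0, p1, radius = r,
                                                  speed = 1 + 0.2 * level)
      if (level < depth) {
        da <- runif(2, 0.25, 0.6)
        grow(p1, angle + da[1], len * 0.7, r * 0.75, level + 1)
        grow(p1, angle - da[2], len * 0.7, r * 0.75, level + 1)
      }
    }
    grow(c(radius * 3, height / 2), runif(1, -0.15, 0.15), width * 0.35,
         radius, 0)
    vessel_network(segs, width, height)
  })
}

# Position, tangent and normal at arclength s on a segment.
.seg_at <- function(seg, s) {
  s <- pmin(pmax(s, 0), seg$length)
  k <- findInterval(s, seg$cumlen, rightmost.closed = TRUE)
  k <- pmin(k, nrow(seg$path) - 1)
  p0 <- seg$path[k, , drop = FALSE]
  p1 <- seg$path[k + 1, , drop = FALSE]
  el <- sqrt(rowSums((p1 - p0)^2))
  f <- (s - seg$cumlen[k]) / el
  pos <- p0 + f * (p1 - p0)
  tang <- (p1 - p0) / el
  list(pos = pos, tangent = tang, normal = cbind(-tang[, 2], tang[, 1]))
}

# Distance from every pixel to a segment's centerline (vectorized over
# edges). The lumen ends flush at the segment endpoints (no protruding end
# caps): tracers travel along the centerline span only, so only the flat-
# ended band is ever perfused. Interior polyline joints are rounded.
.seg_pixel_distance <- function(seg, width, height) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  d <- matrix(Inf, height, width)
  nv <- nrow(seg$path)
  for (k in seq_len(nv - 1)) {
    a <- seg$path[k, ]; b <- seg$path[k + 1, ]
    ab <- b - a; L2 <- sum(ab^2)
    t <- ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / L2
    inside <- t >= 0 & t <= 1
    t <- pmin(pmax(t, 0), 1)
    dk <- sqrt((xs - (a[1] + t * ab[1]))^2 + (ys - (a[2] + t * ab[2]))^2)
    dk[!inside] <- Inf
    d <- pmin(d, dk)
  }
  if (nv > 2) for (k in 2:(nv - 1))   # round the interior joints
    d <- pmin(d, sqrt((xs - seg$path[k, 1])^2 + (ys - seg$path[k, 2])^2))
  d
}

# Lumen thickness (optical path length, px) at lateral offset d from the
# centerline: the chord of the stadium cross-section.
.seg_thickness <- function(seg, d) {
  h <- seg$gap
  Lf <- seg$width - h       # flat span
  out <- numeric(length(d))
  d <- abs(d)
  flat <- d <= Lf / 2
  out[flat] <- h
  cap <- !flat & d <= seg$width / 2
  u <- d[cap] - Lf / 2
  out[cap] <- 2 * sqrt(pmax((h / 2)^2 - u^2, 0))
  out
}

#' Ground-truth vessel mask of a network
#'
#' @param network a [vessel_network()].
#' @return logical `height x width` matrix, `TRUE` inside any rendered lumen.
#' @export
vessel_mask <- function(network) {
  m <- matrix(FALSE, network$height, network$width)
  for (seg in network$segments) {
    d <- .seg_pixel_distance(seg, network$width, network$height)
    m <- m | (d <= seg$width / 2)
  }
  m
}

# Optical-depth map of the lumen relative to local diameter (0..1); used for
# the faint static plasma/wall attenuation.
.thickness_map <- function(network) {
  m <- matrix(0, network$height, network$width)
  for (seg in network$segments) {
    d <- .seg_pixel_distance(seg, network$width, network$height)
    m <- pmax(m, .seg_thickness(seg, d) / (2 * seg$radius))
  }
  m
}

#' Rigid motion, blur and artifact model for synthetic movies
#'
#' Describes the whole-field disturbances of live imaging: periodic rigid
#' jitter (heartbeat), slow drift, intermittent defocus and rare aberrant
#' frames. The defocus schedule blurs exactly `round(blur_fraction * n)`
#' frames at seeded random positions, matching an optical configuration that
#' is out of focus for that fraction of the time (default half).
#'
#' @param jitter_amplitude_px peak rigid jitter along x; the y component uses
#'   half the amplitude with a fixed phase offset.
#' @param jitter_period_frames jitter period in frames.
#' @param drift_px_per_frame length-2 drift vector in px/frame.
#' @param blur_fraction fraction of frames defocused (default 0.5).
#' @param blur_sigma_px Gaussian defocus width in px.
#' @param aberrant_frame_rate probability that a frame is replaced by a
#'   near-saturated aberrant frame (camera glitch).
#' @param seed integer; fully determines the rendered movie.
#' @return a `motion_model` list.
#' @export
motion_model <- function(jitter_amplitude_px = 4, jitter_period_frames = 20,
                         drift_px_per_frame = c(0.02, 0.01),
                         blur_fraction = 0.5, blur_sigma_px = 2.5,
                         aberrant_frame_rate = 0.005, seed = 1) {
  stopifnot(blur_fraction >= 0, blur_fraction <= 1,
            aberrant_frame_rate >= 0, aberrant_frame_rate <= 1)
  structure(list(jitter_amplitude_px = jitter_amplitude_px,
                 jitter_period_frames = jitter_period_frames,
                 drift_px_per_frame = drift_px_per_frame,
                 blur_fraction = blur_fraction,
                 blur_sigma_px = blur_sigma_px,
                 aberrant_frame_rate = aberrant_frame_rate,
                 seed = seed),
            class = "motion_model")
}

#' Static (no-disturbance) motion model
#' @param seed integer seed for tracer placement.
#' @return a [motion_model()] with zero jitter, drift, blur and artifacts.
#' @export
still_motion <- function(seed = 1) {
  motion_model(jitter_amplitude_px = 0, jitter_period_frames = 20,
               drift_px_per_frame = c(0, 0), blur_fraction = 0,
               blur_sigma_px = 0, aberrant_frame_rate = 0, seed = seed)
}

#' Render a synthetic tracer movie with ground truth
#'
#' Erythrocytes are advected along segment centerlines at the segment speed
#' (scaled down by flattening), placed across the lumen with a probability
#' proportional to local optical path length, and rendered as dark
#' anti-aliased discs by multiplicative (Beer-Lambert) absorption: stacked
#' cells darken sub-linearly as in transmission imaging. Each frame is then
#' rigidly displaced by the motion model (jitter + drift, applied
#' analytically, so the ground-truth transform is exact), defocused frames
#' are Gaussian-blurred, aberrant frames are replaced by a near-saturated
#' field, and shot-like Gaussian noise is added.
#'
#' @param network a [vessel_network()].
#' @param motion a [motion_model()]; its seed fully determines the movie.
#' @param n_frames number of frames (>= 2).
#' @param tracer_density tracers per 100 px of centerline.
#' @param contrast absorption depth of one cell in `(0, 1)`: a cell multiplies
#'   the background by `1 - contrast`.
#' @param background mean background intensity.
#' @param cell_radius_px rendered cell radius in px.
#' @param noise_sd additive Gaussian noise sd.
#' @param static_attenuation optical depth of the cell-free lumen (plasma and
#'   wall) at the thickest point; gives the faint static vessel shading seen
#'   in real transmission images.
#' @param background_texture relative amplitude of the static smooth optical
#'   texture of the tissue (the "quasi" in quasi-uniform background: cells,
#'   yolk granularity). This is what anchors registration in real movies;
#'   set to 0 for a featureless field.
#' @return list with `stack` (a [frame_stack()]) and `truth`
#'   (a `movie_ground_truth`: `vessel_mask`, `transforms` data.frame
#'   (frame, dx, dy), `blurred`/`aberrant` flags, `tracers` data.frame
#'   (frame, segment, x, y in scene coordinates), `expected_flux` image and
#'   the generator parameters).
#' @export
render_movie <- function(network, motion, n_frames = 100, tracer_density = 60,
                         contrast = 0.15, background = 0.85,
                         cell_radius_px = 2, noise_sd = 0.005,
                         static_attenuation = 0.1, background_texture = 0.05) {
  stopifnot(n_frames >= 2)
  if (contrast <= 0) stop("contrast must be > 0")
  if (contrast >= 1) stop("contrast must be < 1")
  H <- network$height; W <- network$width
  # saturation advisory: expected cells stacked over a centerline pixel
  lam <- tracer_density / 100 * 2 * cell_radius_px
  if (lam * (-log(1 - contrast)) > 2.5)
    warning("tracer density saturates the vessels in nearly every frame; ",
            "minima projection will be informative only inside vessels")

  with_seed(motion$seed, {
    segs <- network$segments
    nseg <- length(segs)
    ntr <- vapply(segs, function(s) round(tracer_density * s$length / 100), numeric(1))
    # tracer state: segment, arclength, lateral offset
    st <- do.call(rbind, lapply(seq_len(nseg), function(i) {
      n <- ntr[i]
      if (n == 0) return(NULL)
      a <- .sample_lateral(segs[[i]], n)
      cbind(seg = i, s = runif(n, 0, segs[[i]]$length), a = a,
            vf = .speed_factor(segs[[i]], a))
    }))
    if (is.null(st))
      st <- matrix(numeric(0), 0, 4,
                   dimnames = list(NULL, c("seg", "s", "a", "vf")))
    speeds <- vapply(segs, function(s) s$speed * (1 - 0.8 * s$flattening), numeric(1))

    # per-frame transforms and flags
    t0 <- seq_len(n_frames) - 1
    ph <- 2 * pi * t0 / motion$jitter_period_frames
    dx <- motion$jitter_amplitude_px * sin(ph) + motion$drift_px_per_frame[1] * t0
    dy <- 0.5 * motion$jitter_amplitude_px * sin(ph + pi / 3) +
      motion$drift_px_per_frame[2] * t0
    nblur <- round(motion$blur_fraction * n_frames)
    blurred <- rep(FALSE, n_frames)
    blurred[sample.int(n_frames, nblur)] <- TRUE
    aberrant <- runif(n_frames) < motion$aberrant_frame_rate

    od_static <- static_attenuation * .thickness_map(network)
    if (background_texture > 0) {
      tex <- .gauss_blur(matrix(rnorm(H * W), H, W), 2.5)
      tex <- tex / sd(tex) * background_texture
    } else tex <- matrix(0, H, W)

    frames <- array(0, dim = c(H, W, n_frames))
    tracers <- vector("list", n_frames)
    lnc <- -log(1 - contrast)
    for (t in seq_len(n_frames)) {
      pt <- .seg_at_multi(segs, st)
      tracers[[t]] <- data.frame(frame = rep(t, nrow(st)),
                                 segment = st[, "seg"],
                                 x = pt[, 1], y = pt[, 2])
      if (aberrant[t]) {
        fr <- matrix(0.98, H, W)
      } else {
        # background and static lumen shading, evaluated in shifted coordinates
        bx <- 1 + 0.04 * ((seq_len(W) - dx[t]) - (W + 1) / 2) / W
        by <- 1 + 0.03 * ((seq_len(H) - dy[t]) - (H + 1) / 2) / H
        fr <- background * (by %o% bx)
        fr <- fr * (1 + .bilinear_shift_matrix(tex, dx[t], dy[t], fill = 0))
        fr <- fr * exp(-.bilinear_shift_matrix(od_static, dx[t], dy[t], fill = 0))
        cnt <- .stamp_counts(pt[, 1] + dx[t], pt[, 2] + dy[t],
                             cell_radius_px, H, W)
        fr <- fr * exp(-lnc * cnt)
        if (blurred[t] && motion$blur_sigma_px > 0)
          fr <- .gauss_blur(fr, motion$blur_sigma_px)
      }
      if (noise_sd > 0) fr <- fr + matrix(rnorm(H * W, 0, noise_sd), H, W)
      frames[, , t] <- pmin(pmax(fr, 0), 1)
      # advect; resample lateral position when a tracer wraps around
      st[, "s"] <- st[, "s"] + speeds[st[, "seg"]] * st[, "vf"]
      wrap <- st[, "s"] >= vapply(segs, `[[`, numeric(1), "length")[st[, "seg"]]
      if (any(wrap)) {
        st[wrap, "s"] <- st[wrap, "s"] %%
          vapply(segs, `[[`, numeric(1), "length")[st[wrap, "seg"]]
        for (i in unique(st[wrap, "seg"])) {
          rows <- wrap & st[, "seg"] == i
          a <- .sample_lateral(segs[[i]], sum(rows))
          st[rows, "a"] <- a
          st[rows, "vf"] <- .speed_factor(segs[[i]], a)
        }
      }
    }

    truth <- structure(list(
      vessel_mask = vessel_mask(network),
      transforms = data.frame(frame = seq_len(n_frames), dx = dx, dy = dy),
      blurred = blurred, aberrant = aberrant,
      tracers = do.call(rbind, tracers),
      expected_flux = .expected_flux_image(network, ntr, cell_radius_px, lnc),
      network = network,
      params = list(n_frames = n_frames, tracer_density = tracer_density,
                    contrast = contrast, background = background,
                    cell_radius_px = cell_radius_px, noise_sd = noise_sd,
                    static_attenuation = static_attenuation, motion = motion)),
      class = "movie_ground_truth")
    list(stack = frame_stack(frames), truth = truth)
  })
}

# Lateral offsets sampled with density proportional to lumen thickness
# (cells fill the cross-section uniformly in 3D; the projection weights
# lateral position by chord length).
# Per-tracer lognormal speed dispersion. Makes the tracer pattern
# decorrelate over tens of frames, as real erythrocyte trains do; without it
# the whole pattern would translate rigidly forever and any registration
# could lock onto the flow. Deliberately independent of lateral position:
# a transverse velocity profile would make slow near-wall cells over-occupy
# the lumen edges and distort the chord-law occupancy that minima
# profilometry relies on.
.speed_factor <- function(seg, a) {
  exp(rnorm(length(a), 0, 0.12))
}

.sample_lateral <- function(seg, n) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  hw <- seg$width / 2
  while (length(out) < n) {
    cand <- runif(2 * n + 8, -hw, hw)
    keep <- runif(length(cand)) < .seg_thickness(seg, cand) / seg$gap
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

# Positions of all tracers (rows of state matrix) in scene coordinates.
.seg_at_multi <- function(segs, st) {
  out <- matrix(0, nrow(st), 2)
  for (i in unique(st[, "seg"])) {
    rows <- st[, "seg"] == i
    at <- .seg_at(segs[[i]], st[rows, "s"])
    out[rows, ] <- at$pos + st[rows, "a"] * at$normal
  }
  out
}

# Accumulate anti-aliased disc coverage counts for all tracers into an image.
.stamp_counts <- function(px, py, r, H, W) {
  cnt <- matrix(0, H, W)
  if (length(px) == 0) return(cnt)
  m <- ceiling(r) + 1
  off <- as.matrix(expand.grid(oy = -m:m, ox = -m:m))
  n <- length(px)
  cx <- rep(round(px), each = nrow(off)) + rep(off[, "ox"], n)
  cy <- rep(round(py), each = nrow(off)) + rep(off[, "oy"], n)
  dx <- cx - rep(px, each = nrow(off))
  dy <- cy - rep(py, each = nrow(off))
  cov <- pmin(pmax(r + 0.5 - sqrt(dx^2 + dy^2), 0), 1)
  ok <- cov > 0 & cx >= 1 & cx <= W & cy >= 1 & cy <= H
  if (!any(ok)) return(cnt)
  idx <- (cx[ok] - 1) * H + cy[ok]
  sums <- rowsum(cov[ok], idx)
  cnt[as.integer(rownames(sums))] <- sums
  cnt
}

# Expected per-frame absorption image (mean tracer occupancy times per-cell
# optical depth), computed from the generator's own stationary distribution.
# Sampling is chunked to bound memory at high tracer densities.
.expected_flux_image <- function(network, ntr, r, lnc, samples_per_tracer = 400) {
  H <- network$height; W <- network$width
  acc <- matrix(0, H, W)
  for (i in seq_along(network$segments)) {
    if (ntr[i] == 0) next
    seg <- network$segments[[i]]
    K <- min(max(2000, samples_per_tracer * ntr[i]), 100000)
    done <- 0
    while (done < K) {
      k <- min(20000, K - done)
      s <- runif(k, 0, seg$length)
      a <- .sample_lateral(seg, k)
      at <- .seg_at(seg, s)
      p <- at$pos + a * at$normal
      acc <- acc + .stamp_counts(p[, 1], p[, 2], r, H, W) * (ntr[i] / K)
      done <- done + k
    }
  }
  acc * lnc
}

#' @export
print.movie_ground_truth <- function(x, ...) {
  cat(sprintf("<movie_ground_truth> %d frames, %d blurred, %d aberrant, %d tracer tracks\n",
              nrow(x$transforms), sum(x$blurred), sum(x$aberrant),
              nrow(x$tracers) / nrow(x$transforms)))
  invisible(x)
}

#' Write ground truth sidecar files
#'
#' Mask as single-page TIFF, transforms and tracer tracks as CSV (pixel
#' coordinates are written 0-based for interoperability).
#'
#' @param truth a `movie_ground_truth` from [render_movie()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(truth$vessel_mask * 1, file.path(dir, "vessel_mask.tif"),
                  bits.per.sample = 8L)
  tr <- truth$transforms
  tr$blurred <- truth$blurred
  tr$aberrant <- truth$aberrant
  write.csv(tr, file.path(dir, "transforms.csv"), row.names = FALSE)
  tk <- truth$tracers
  tk$x <- tk$x - 1; tk$y <- tk$y - 1
  write.csv(tk, file.path(dir, "tracers.csv"), row.names = FALSE)
  invisible(dir)
}
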