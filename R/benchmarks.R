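#' Standard synthetic benchmarks
#'
#' Two fully seeded study configurations used throughout the package's tests
#' and validation scripts.
#'
#' `pipeline_benchmark()` emulates a realistic acquisition for the stack
#' pipeline: a vessel field with a cylindrical trunk, a flattened terminal
#' segment and an oblique branch, imaged for `n_frames` frames at the
#' generator defaults (moderate tracer density, heartbeat jitter of 4 px at a
#' 20-frame period, slow drift, half the frames defocused, rare aberrant
#' frames).
#'
#' `profile_benchmark()` emulates the maximal-absorption profilometry
#' regime: a motionless field with one cylindrical and one fully flattened
#' straight vessel (radius 7 px), imaged long enough, and with a dense
#' low-contrast erythrocyte load, that every lumen column is completely
#' filled many times — the condition under which the minima image's optical
#' density approaches the cross-section chord. Background texture is nearly
#' off, matching the background-flattened images profiles are read from.
#'
#' @param seed integer seed: determines everything.
#' @param n_frames number of frames.
#' @return list with `stack`, `truth` (see [render_movie()]); for
#'   `profile_benchmark` also `radius` (7) and the `round_line`/`flat_line`
#'   profile lines through the two vessels.
#' @export
pipeline_benchmark <- function(seed = 1, n_frames = 300) {
  net <- vessel_network(list(
    vessel_segment(c(20, 45), c(88, 45), radius = 6, flattening = 0, speed = 1.6),
    vessel_segment(c(88, 45), c(150, 45), radius = 6, flattening = 1, speed = 1.6),
    vessel_segment(c(88, 45), c(140, 85), radius = 4, flattening = 0, speed = 1.2)),
    width = 176, height = 120)
  render_movie(net, motion_model(seed = seed), n_frames = n_frames)
}

#' @rdname pipeline_benchmark
#' @export
profile_benchmark <- function(seed = 1, n_frames = 220) {
  net <- vessel_network(list(
    vessel_segment(c(20, 30), c(120, 30), radius = 7, flattening = 0, speed = 1.5),
    vessel_segment(c(20, 70), c(120, 70), radius = 7, flattening = 1, speed = 1.5)),
    width = 140, height = 104)
  mov <- suppressWarnings(render_movie(
    net, still_motion(seed = seed), n_frames = n_frames,
    tracer_density = 4500, contrast = 0.03, cell_radius_px = 2,
    noise_sd = 0.003, static_attenuation = 0.1, background_texture = 0.01))
  mov$radius <- 7
  mov$round_line <- profile_line(70, 8, 70, 52)
  mov$flat_line <- profile_line(70, 48, 70, 92)
  mov
}
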