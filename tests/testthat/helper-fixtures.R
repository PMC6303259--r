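# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# 300-frame stack benchmark: jitter, drift, 50% defocus, rare aberrant frames.
fix_pipeline_movie <- function() {
  fixture("pipeline_movie", function() pipeline_benchmark(seed = 1, n_frames = 300))
}

# Default (fixed-reference) pipeline run on the benchmark.
fix_pipeline_run <- function() {
  fixture("pipeline_run", function() run_pipeline(fix_pipeline_movie()$stack))
}

# Benchmark runs under consecutive-frame ("previous") registration, with and
# without the decorrelation shuffle — the ablation pair.
fix_prev_run <- function(shuffle) {
  name <- if (shuffle) "prev_run_shuffled" else "prev_run_plain"
  fixture(name, function()
    run_pipeline(fix_pipeline_movie()$stack, reference = "previous",
                 shuffle = shuffle))
}

# Dense saturated profilometry benchmark and its minima projection.
fix_profile_movie <- function() {
  fixture("profile_movie", function() profile_benchmark(seed = 11))
}

fix_profile_minima <- function() {
  fixture("profile_minima", function() project(fix_profile_movie()$stack, "minima"))
}

# Small motion-free movie for cheap stack-processing tests.
fix_small_movie <- function() {
  fixture("small_movie", function() {
    net <- vessel_network(list(
      vessel_segment(c(15, 30), c(85, 30), radius = 5, speed = 1.5)),
      width = 100, height = 60)
    render_movie(net, still_motion(seed = 4), n_frames = 40)
  })
}

# Ground-truth-aligned Dice of a pipeline result against the true mask:
# the truth mask lives in scene coordinates, the result in the reference
# frame's coordinates, so the truth is shifted by the reference frame's
# known transform before comparison.
dice_vs_truth <- function(res, truth) {
  ref <- which(res$registration$dx == 0 & res$registration$dy == 0)[1]
  racq <- res$registration$acq_index[ref]
  tr <- truth$transforms
  shifted <- capiflow:::.bilinear_shift_matrix(
    truth$vessel_mask * 1, tr$dx[racq], tr$dy[racq], fill = 0) > 0.5
  dice(res$mask, shifted)
}

# Registration errors (px) of a pipeline result against ground truth.
registration_errors <- function(res, truth) {
  reg <- res$registration
  tr <- truth$transforms
  ref <- which(reg$dx == 0 & reg$dy == 0)[1]
  gt <- tr[reg$acq_index, ]
  sqrt((reg$dx - (gt$dx - gt$dx[ref]))^2 + (reg$dy - (gt$dy - gt$dy[ref]))^2)
}

# Minimal two-page grayscale TIFF with mismatched bit depths (8 then 16),
# which no common writer produces but the reader must reject.
make_mixed_depth_tiff <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    w16(id); w16(type); w32(count)
    if (type == 3) { w16(value); w16(0) } else w32(value)
  }
  ifd_size <- 2 + 9 * 12 + 4
  ifd1 <- 8; ifd2 <- ifd1 + ifd_size
  data1 <- ifd2 + ifd_size; data2 <- data1 + 4
  writeChar("II", con, eos = NULL); w16(42); w32(ifd1)
  ifd <- function(bits, strip_off, nbytes, next_off) {
    w16(9)
    tag(256, 3, 1, 2); tag(257, 3, 1, 2); tag(258, 3, 1, bits)
    tag(259, 3, 1, 1); tag(262, 3, 1, 1); tag(273, 4, 1, strip_off)
    tag(277, 3, 1, 1); tag(278, 3, 1, 2); tag(279, 4, 1, nbytes)
    w32(next_off)
  }
  ifd(8, data1, 4, ifd2)
  ifd(16, data2, 8, 0)
  writeBin(as.raw(c(10, 200, 30, 250)), con)
  writeBin(as.integer(c(1000, 40000, 2000, 60000)), con, size = 2,
           endian = "little")
  invisible(path)
}
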