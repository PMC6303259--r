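#' Default pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] into a plain list that
#' serializes losslessly to YAML, so a saved configuration re-runs to
#' identical outputs.
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    shuffle = TRUE,
    keep_fraction = 0.5,
    blur_method = "auto",
    roi = NULL,
    aberrant_threshold = 0.2,
    register_model = "translation",
    reference = "fixed",
    reference_slot = NULL,
    flatten_radius = NULL,
    seed = 1,
    fps = NA_real_
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, over, keep.null = TRUE), class = "run_config")
}

#' Read / write a pipeline configuration
#' @param path YAML file path.
#' @return a `run_config` (for `read_run_config`) or `path` invisibly.
#' @export
read_run_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a [pipeline_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable checksum of an image/stack after 16-bit quantization (so float
# round-off cannot change it across platforms).
.image_checksum <- function(x) {
  q <- as.integer(round(pmin(pmax(x, 0), 1) * 65535))
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(q, f, size = 4L, endian = "little")
  unname(tools::md5sum(f))
}

#' Run the full stack-processing pipeline
#'
#' Executes the canonical processing order: decorrelation shuffle, blur
#' rejection, aberrant-frame rejection, registration, unshuffle, minima and
#' average projection, optional background flattening, and Otsu vessel
#' masking of the minima image. Shuffling comes first because registration
#' must see decorrelated tracers; unshuffling after registration restores a
#' smooth, aligned movie for PIV.
#'
#' @param stack a [frame_stack()], or a path to a multi-page TIFF.
#' @param config a [pipeline_config()]; individual fields can be overridden
#'   through `...`.
#' @param out_dir optional directory: projections (16-bit TIFF), mask, the
#'   per-frame log (CSV) and the manifest (JSON) are written there.
#' @param ... config overrides, e.g. `shuffle = FALSE` for the ablation run.
#' @return list with `minima`, `average` (projection images), `mask`,
#'   `registration` (per-frame log), `stack` (registered,
#'   acquisition-ordered) and `manifest` (stage frame counts, parameters,
#'   checksums).
#' @export
run_pipeline <- function(stack, config = pipeline_config(), out_dir = NULL, ...) {
  if (is.character(stack)) stack <- read_stack(stack)
  config <- structure(modifyList(config, list(...), keep.null = TRUE),
                      class = "run_config")
  n0 <- n_frames(stack)
  stages <- list(acquired = n0)

  perm <- NULL
  if (isTRUE(config$shuffle)) {
    sh <- shuffle_decorrelate(stack)
    stack <- sh$stack; perm <- sh$permutation
  }
  stack <- filter_blurred(stack, roi = config$roi,
                          keep_fraction = config$keep_fraction,
                          method = config$blur_method)
  stages$after_blur_filter <- n_frames(stack)
  stack <- discard_aberrant(stack, max_distance = config$aberrant_threshold)
  stages$after_aberrant_filter <- n_frames(stack)
  reg <- register_stack(stack, reference_slot = config$reference_slot,
                        model = config$register_model,
                        reference = config$reference)
  stack <- unshuffle(reg$stack, perm)
  stages$projected <- n_frames(stack)

  minima <- project(stack, "minima")
  average <- project(stack, "average")
  if (!is.null(config$flatten_radius)) {
    minima <- flatten_background(minima, config$flatten_radius)
    average <- flatten_background(average, config$flatten_radius)
  }
  mask <- otsu_mask(minima)

  manifest <- list(
    stages = stages,
    decorrelation = isTRUE(config$shuffle),
    config = unclass(config),
    checksums = list(minima = .image_checksum(minima$image),
                     average = .image_checksum(average$image),
                     mask = .image_checksum(mask * 1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_projection(minima, file.path(out_dir, "minima.tif"))
    write_projection(average, file.path(out_dir, "average.tif"))
    tiff::writeTIFF(mask * 1, file.path(out_dir, "mask.tif"),
                    bits.per.sample = 8L)
    write.csv(reg$result, file.path(out_dir, "frames.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  list(minima = minima, average = average, mask = mask,
       registration = reg$result, stack = stack, manifest = manifest)
}
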