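# Nested pipeline configuration with JSON round trip and strict key
# validation. The defaults describe the reference instrument: NA 1.4,
# 491/525 nm, 100.8x total magnification, 237 nm pattern period at
# 41/101/161 degrees with 5 phases, 7 planes at 264 nm and 11% of the
# emission per plane, a 1600 x 1600 crop and 8.5 ms readout.

#' Full pipeline configuration
#'
#' Bundles the optical, illumination, multifocus, camera and timing
#' configuration plus reconstruction options and the seed. Any field can
#' be overridden through nested lists; unknown keys are rejected.
#'
#' @param optical,pattern,multifocus,camera,timing Named lists of
#'   overrides for the respective constructors.
#' @param recon Named list of reconstruction options
#'   (`w`, `apod`, `notch_depth`, `upsample`).
#' @param seed Integer seed.
#' @return Object of class `pipeline_config` with instantiated
#'   configuration objects.
#' @export
pipeline_config <- function(optical = list(), pattern = list(),
                            multifocus = list(), camera = list(),
                            timing = list(), recon = list(), seed = 1) {
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")))
  }
  check_keys(optical, names(formals(optical_config)), "optical")
  check_keys(pattern, names(formals(illumination_pattern)), "pattern")
  check_keys(multifocus, names(formals(multifocus_config)), "multifocus")
  check_keys(camera, names(formals(camera_config)), "camera")
  check_keys(timing, names(formals(acquisition_timing)), "timing")
  check_keys(recon, c("w", "apod", "notch_depth", "upsample"), "recon")

  cfg <- do.call(optical_config, optical)
  pat <- do.call(illumination_pattern, pattern)
  mf <- do.call(multifocus_config, multifocus)
  cam <- do.call(camera_config,
                 c(camera, if (is.null(camera$frame_px))
                   list(frame_px = mf$frame_px)))
  if (is.null(timing$exposure_ms)) timing$exposure_ms <- 20
  if (is.null(timing$n_frames_per_volume))
    timing$n_frames_per_volume <- length(pat$orientations) * pat$n_phases
  tim <- do.call(acquisition_timing, timing)
  rec <- utils::modifyList(list(w = 0.05, apod = "triangle",
                                notch_depth = 0.92, upsample = 2), recon)
  structure(list(optical = cfg, pattern = pat, multifocus = mf,
                 camera = cam, timing = tim, recon = rec,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' The JSON holds only the override lists, so a round trip through
#' [write_pipeline_config()] and [read_pipeline_config()] reproduces the
#' configuration exactly; unknown keys in the file are rejected.
#'
#' @param overrides Named list with any of `optical`, `pattern`,
#'   `multifocus`, `camera`, `timing`, `recon`, `seed`.
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(obj), c("optical", "pattern", "multifocus", "camera",
                               "timing", "recon", "seed"))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, obj)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(overrides, path) {
  jsonlite::write_json(overrides, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
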