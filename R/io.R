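# File formats and fixtures. Image stacks travel as multi-page 32-bit-float
# TIFF plus a JSON metadata sidecar (frame rate, pixel size, intensity
# scale); designs as JSON; traces, features, maps, and endpoint records as
# CSV; run configuration as YAML.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a frame stack as multi-page TIFF + JSON sidecar
#'
#' Intensities are stored as 32-bit floats scaled to [0, 1] by the recorded
#' maximum; the scale, frame rate, and pixel size live in the sidecar so the
#' round trip restores the original values (to single precision).
#'
#' @param stack A [frame_stack()].
#' @param path Output `.tif` path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  sc <- max(stack$intensities)
  if (sc <= 0) sc <- 1
  frames <- lapply(seq_len(dim(stack$intensities)[3L]),
                   function(f) stack$intensities[, , f] / sc)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  meta <- list(format = "spiralmap_frame_stack", version = 1L,
               frame_rate_hz = stack$frame_rate,
               pixel_size_um = stack$pixel_size,
               intensity_scale = sc,
               n_frames = length(frames),
               design_id = stack$design_id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param path The `.tif` path; the JSON sidecar must sit next to it -
#'   missing metadata is an explicit error, never silently defaulted.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path))
    sm_stop("format_error", "no such file: %s", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    sm_stop("missing_metadata",
            "metadata sidecar %s not found; frame rate and pixel size are required", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (field in c("frame_rate_hz", "pixel_size_um", "intensity_scale"))
    if (is.null(meta[[field]]))
      sm_stop("missing_metadata", "sidecar lacks required field `%s`", field)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) sm_stop("format_error",
                                                 "cannot read TIFF %s: %s", path,
                                                 conditionMessage(e)))
  if (!is.list(frames)) frames <- list(frames)
  if (!is.null(meta$n_frames) && length(frames) != meta$n_frames)
    sm_stop("format_error", "expected %d frames, found %d (truncated file?)",
            meta$n_frames, length(frames))
  arr <- array(unlist(frames), dim = c(dim(frames[[1L]]), length(frames)))
  frame_stack(arr * meta$intensity_scale,
              frame_rate = meta$frame_rate_hz,
              pixel_size = meta$pixel_size_um,
              design_id = meta$design_id)
}

#' Serialize a spiral design to JSON
#'
#' All defining parameters are written explicitly with units; the sampled
#' centerline is reconstructed on read and checked against the stored total
#' length.
#'
#' @param design A `spiral_design`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  validate_spiral_design(design)
  jsonlite::write_json(list(
    format = "spiralmap_design", version = 1L,
    d_l_um = design$d_l, d_s_um = design$d_s, pitch_um = design$pitch,
    n_turns = design$n_turns, r0_um = design$r0,
    sampling_step_um = design$sampling_step,
    total_length_cm = design$total_length_cm
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spiral design written by [write_design()]
#'
#' @param path The `.json` path.
#' @return A `spiral_design`.
#' @export
read_design <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "spiralmap_design")
    sm_stop("format_error", "%s is not a spiral design file", path)
  d <- build_spiral(meta$d_l_um, meta$d_s_um, meta$n_turns, meta$r0_um,
                    sampling_step = meta$sampling_step_um, pitch = meta$pitch_um)
  if (abs(d$total_length_cm - meta$total_length_cm) > 1e-6 * meta$total_length_cm)
    sm_stop("format_error",
            "reconstructed length %.6f cm disagrees with stored %.6f cm",
            d$total_length_cm, meta$total_length_cm)
  d
}

#' Default run configuration
#'
#' Every analysis threshold in one place, each defaulting to the
#' documented value of the processing chain: the 0.005 spatial Butterworth
#' cutoff, the 80% wave-amplitude threshold, the 10-wave minimum, the
#' 50%-upstroke activation level, the 150 Hz slice low-pass, the 7x7
#' spatial average, the line-scan smoother, and the classifier rule set.
#'
#' @param seed Integer seed.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    design = list(d_l_um = 200, d_s_um = 400,
                  n_turns = .SPIRAL_DEFAULT_N_TURNS, r0_um = .SPIRAL_DEFAULT_R0,
                  sampling_step_um = 25),
    simulation = list(cv_cm_s = 20, apd80_ms = 180, cycle_length_ms = 500,
                      n_frames = 300L, frame_rate_hz = 30, pixel_size_um = 40,
                      dye_fraction = 0.02, noise_sd = 0.005,
                      bleach_rate_per_s = 0.002),
    analysis = list(spatial_cutoff = 0.005, spatial_order = 3L,
                    wave_threshold = 0.8, min_waves = 10L,
                    extraction_width_px = 10L, arc_step_cm = 0.001,
                    linescan_lowpass_hz = 40, linescan_median_window = 5L,
                    activation_level = 0.5, slice_lowpass_hz = 150,
                    slice_spatial_px = 7L, rule_set = "text"),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Round-trips losslessly.
#' @param config A `run_config` list.
#' @param path `.yaml` path.
#' @return `path` / the `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Generate the bundled miniature fixture set
#'
#' Deterministic small versions of every input kind, used by the test suite
#' and the worked examples: a spiral movie (TIFF + sidecar), a line-scan
#' pair (CSV), an MEA recording (CSV), a patch-clamp trace (CSV), an S1-S2
#' capture scan (CSV), the design (JSON), and a manifest (JSON) listing all
#' embedded ground-truth values.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the same seed reproduces identical files.
#' @return The manifest, invisibly (list with file names and ground truth).
#' @export
make_fixtures <- function(dir = tempfile("spiralmap_fixtures"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- default_design()
  write_design(design, file.path(dir, "design.json"))
  cfg <- spiral_sim_config(cv = 20, apd80 = 180, n_frames = 120L,
                           pixel_size = 60, seed = seed)
  stack <- simulate_spiral_recording(design, cfg)
  write_stack(stack, file.path(dir, "spiral_movie.tif"))
  ls <- simulate_linescan(design, cfg, c(0.1, 0.3), c(5.2, 5.4))
  utils::write.csv(data.frame(time_ms = ls$trace_a$time_ms,
                              region_a = ls$trace_a$value,
                              region_b = ls$trace_b$value),
                   file.path(dir, "linescan.csv"), row.names = FALSE)
  mea <- simulate_mea(cv = 8.8, mode = "point_source", seed = seed,
                      sample_rate = 2000, n_beats = 1L)
  mea_df <- as.data.frame(mea$traces)
  names(mea_df) <- sprintf("e%02d", seq_len(ncol(mea_df)))
  utils::write.csv(cbind(time_ms = mea$time_ms, mea_df),
                   file.path(dir, "mea.csv"), row.names = FALSE)
  patch <- simulate_patch_ap(noise_sd_mv = 0.2, seed = seed, sample_rate = 2000)
  utils::write.csv(patch, file.path(dir, "patch_atrial.csv"), row.names = FALSE)
  model <- restitution_model(apd_max = 210, capture_threshold_di = 38)
  scan <- simulate_s1s2(model)
  utils::write.csv(scan, file.path(dir, "s1s2_scan.csv"), row.names = FALSE)
  manifest <- list(
    seed = seed,
    design = list(file = "design.json", total_length_cm = design$total_length_cm),
    spiral_movie = list(file = "spiral_movie.tif", cv_cm_s = cfg$cv,
                        apd80_ms = cfg$apd80,
                        supra80_extent_cm = cfg$cv * stack$truth$supra80_duration_ms / 1000),
    linescan = list(file = "linescan.csv", cv_cm_s = cfg$cv, apd80_ms = cfg$apd80,
                    separation_cm = ls$separation_cm,
                    frame_rate_hz = ls$frame_rate),
    mea = list(file = "mea.csv", cv_cm_s = 8.8, electrode_pitch_um = 450,
               sample_rate_hz = 2000),
    patch = list(file = "patch_atrial.csv", mdp_mv = -63.9, apa_mv = 110,
                 dvdt_max_v_s = 27.1, apd90_ms = 294.6, apd_ratio = 1.34),
    s1s2 = list(file = "s1s2_scan.csv",
                erp_continuum_ms = attr(scan, "erp_continuum"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
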