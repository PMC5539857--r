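#' Pipeline configuration
#'
#' One configuration object drives the full simulate-segment-estimate
#' pipeline. It round-trips losslessly through JSON
#' ([write_pipeline_config()] / [read_pipeline_config()]), so a run can be
#' reproduced bit-identically from the configuration echoed in its run
#' report.
#'
#' @param scan_config A [scan_set_config()].
#' @param threshold_db Segmentation threshold, dB (negative).
#' @param closing_radius Closing radii `c(axial, lateral)`, pixels.
#' @param connectivity Component connectivity, 4 or 8.
#' @param attenuation Attenuation source for the backscatter stage: a fixed
#'   value in dB/mm, or `"estimated"` to measure it from the scan set's
#'   reference pair.
#' @param thicknesses Thickness sweep for the impedance-vs-thickness curve,
#'   mm.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scan_config = scan_set_config(),
                            threshold_db = -26, closing_radius = c(3, 2),
                            connectivity = 8, attenuation = "estimated",
                            thicknesses = c(0.5, 1, 1.5, 2, 2.5, 3),
                            seed = 1) {
  structure(
    list(
      scan_config = scan_config, threshold_db = threshold_db,
      closing_radius = closing_radius, connectivity = connectivity,
      attenuation = attenuation, thicknesses = thicknesses,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Serialise / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scan_config
  pl <- sc$pulse
  out <- list(
    pulse = list(
      center_frequency = pl$center_frequency,
      fractional_bandwidth = pl$fractional_bandwidth,
      sampling_rate = pl$sampling_rate, amplitude = pl$amplitude
    ),
    phantom = list(
      layers = lapply(sc$phantom$layers, unclass),
      coupling_impedance = sc$phantom$coupling_impedance,
      coupling_sound_speed = sc$phantom$coupling_sound_speed,
      standoff = sc$phantom$standoff,
      substrate_impedance = sc$phantom$substrate_impedance
    ),
    reference_slab = unclass(sc$reference_slab),
    acquisition = list(
      n_lines = sc$n_lines, line_pitch = sc$line_pitch,
      noise_sd = sc$noise_sd, transmission = sc$transmission,
      quartz_impedance = sc$quartz_impedance
    ),
    segmentation = list(
      threshold_db = config$threshold_db,
      closing_radius = config$closing_radius,
      connectivity = config$connectivity
    ),
    attenuation = config$attenuation,
    thicknesses = config$thicknesses,
    seed = config$seed
  )
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(x$phantom$layers, function(l) {
    tissue_layer(l$name, l$thickness, l$impedance, l$attenuation,
                 l$backscatter_strength, l$scatterer_density, l$sound_speed)
  })
  phantom <- layered_phantom(
    layers,
    coupling_impedance = x$phantom$coupling_impedance,
    coupling_sound_speed = x$phantom$coupling_sound_speed,
    standoff = x$phantom$standoff,
    substrate_impedance = x$phantom$substrate_impedance
  )
  rs <- x$reference_slab
  slab <- tissue_layer(rs$name, rs$thickness, rs$impedance, rs$attenuation,
                       rs$backscatter_strength, rs$scatterer_density,
                       rs$sound_speed)
  sc <- scan_set_config(
    phantom = phantom,
    pulse = acoustic_pulse(x$pulse$center_frequency, x$pulse$fractional_bandwidth,
                           x$pulse$sampling_rate, x$pulse$amplitude),
    n_lines = x$acquisition$n_lines, line_pitch = x$acquisition$line_pitch,
    noise_sd = x$acquisition$noise_sd,
    transmission = x$acquisition$transmission,
    quartz_impedance = x$acquisition$quartz_impedance,
    reference_slab = slab
  )
  pipeline_config(
    scan_config = sc, threshold_db = x$segmentation$threshold_db,
    closing_radius = unlist(x$segmentation$closing_radius),
    connectivity = x$segmentation$connectivity,
    attenuation = if (identical(x$attenuation, "estimated")) "estimated"
                  else as.numeric(x$attenuation),
    thicknesses = unlist(x$thicknesses), seed = x$seed
  )
}

#' Simulate a scan set and write it to disk
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return List with the scan-set path and the run-report path, invisibly;
#'   the run report (JSON) echoes the configuration and records every output.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ss <- generate_scan_set(config$scan_config, seed = config$seed)
  ss_dir <- file.path(out_dir, "scan_set")
  write_scan_set(ss, ss_dir)
  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  report <- list(
    stage = "simulate", seed = config$seed, config = cfg_path,
    outputs = list(scan_set = ss_dir),
    package_version = as.character(utils::packageVersion("qusim"))
  )
  rp <- file.path(out_dir, "run_report.json")
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE), rp)
  invisible(list(scan_set = ss_dir, report = rp))
}

#' Run segmentation and QUS estimation over a scan set
#'
#' Segments the sample scan, calibrates the incident amplitude from the
#' quartz echo, and writes per-line and summary CSV/JSON for impedance,
#' attenuation (measured from the reference pair or fixed by configuration),
#' backscatter coefficient, and the impedance-vs-thickness sweep.
#'
#' @param scan_set Path to a scan-set directory, or a `scan_set` object.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisible list of the result objects and output paths.
#' @export
run_qus <- function(scan_set, config = pipeline_config(), out_dir) {
  if (is.character(scan_set)) scan_set <- read_scan_set(scan_set)
  stopifnot(inherits(scan_set, "scan_set"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  seg <- segment_roi(scan_set$sample_scan,
    threshold_db = config$threshold_db,
    closing_radius = config$closing_radius,
    connectivity = config$connectivity
  )
  cal <- calibration_from_scan_set(scan_set)
  z <- estimate_impedance_scan(seg, cal)
  alpha <- if (identical(config$attenuation, "estimated")) {
    attenuation_estimate(attenuation_from_reference(list(
      with_tissue = scan_set$reference_with_tissue,
      without = scan_set$reference_no_tissue
    )))
  } else {
    attenuation_estimate(as.numeric(config$attenuation))
  }
  bsc <- estimate_bsc_scan(seg, cal, alpha)
  sweep <- impedance_vs_thickness(seg, cal, config$thicknesses)

  readr::write_csv(tidy(z), file.path(out_dir, "impedance_per_line.csv"))
  readr::write_csv(tidy(bsc), file.path(out_dir, "bsc_per_line.csv"))
  readr::write_csv(
    dplyr::select(sweep, -"estimate"),
    file.path(out_dir, "impedance_vs_thickness.csv")
  )
  write_mask_csv(seg$mask, file.path(out_dir, "roi_mask_rle.csv"), format = "rle")
  summary <- list(
    impedance = as.list(glance(z)),
    attenuation = as.list(glance(alpha)),
    bsc = as.list(glance(bsc)),
    warnings = list(skipped_lines = z$n_skipped)
  )
  writeLines(
    jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     na = "null"),
    file.path(out_dir, "qus_summary.json")
  )
  report <- list(
    stage = "qus", seed = scan_set$seed,
    segmentation = list(
      threshold_db = config$threshold_db,
      closing_radius = config$closing_radius,
      connectivity = config$connectivity,
      regions_before_selection = seg$mask$region_count_before_selection,
      d1_mm = seg$mask$d1, d2_mm = seg$mask$d2
    ),
    outputs = list(
      impedance_per_line = "impedance_per_line.csv",
      bsc_per_line = "bsc_per_line.csv",
      impedance_vs_thickness = "impedance_vs_thickness.csv",
      roi_mask = "roi_mask_rle.csv",
      summary = "qus_summary.json"
    ),
    package_version = as.character(utils::packageVersion("qusim"))
  )
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_report.json"))
  invisible(list(segmented = seg, impedance = z, attenuation = alpha,
                 bsc = bsc, sweep = sweep, out_dir = out_dir))
}

#' Derive the transducer output table from a drive CSV
#'
#' Reads a CSV with columns `vpp`, `p_ac_mw`, `pressure_kpa`, derives input
#' power, efficiency, intensity and mechanical index, and writes the full
#' table plus a JSON summary.
#'
#' @param csv_path Input CSV path.
#' @param out_dir Output directory.
#' @param frequency Drive frequency, MHz.
#' @param beam_diameter -6 dB beam diameter, mm.
#' @param impedance Electrical impedance magnitude, Ohm.
#' @return The derived `transducer_output_table`, invisibly.
#' @export
run_transducer_table <- function(csv_path, out_dir, frequency = 4,
                                 beam_diameter = 2.70,
                                 impedance = focused_transducer_impedance) {
  x <- readr::read_csv(csv_path, show_col_types = FALSE)
  if (!"vpp" %in% names(x)) abort("Drive CSV needs a `vpp` column.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- build_output_table(x, beam_diameter = beam_diameter,
                            frequency = frequency, impedance = impedance)
  readr::write_csv(tab, file.path(out_dir, "transducer_output_table.csv"))
  writeLines(
    jsonlite::toJSON(as.list(glance(tab)), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE),
    file.path(out_dir, "transducer_summary.json")
  )
  invisible(tab)
}

#' Summarise a TER experiment from CSV
#'
#' @param csv_path TER CSV (schema of [generate_ter_series()]).
#' @param out_dir Output directory.
#' @param baseline_window End of the baseline window, minutes.
#' @param recovery_tolerance Fractional recovery tolerance.
#' @return The `ter_summary`, invisibly.
#' @export
run_ter <- function(csv_path, out_dir, baseline_window = 5,
                    recovery_tolerance = 0.01) {
  series <- read_ter_csv(csv_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- summarize_conditions(series, baseline_window, recovery_tolerance)
  readr::write_csv(summary, file.path(out_dir, "ter_condition_summary.csv"))
  readr::write_csv(tidy(summary), file.path(out_dir, "ter_per_well.csv"))
  invisible(summary)
}
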