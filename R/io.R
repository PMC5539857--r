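#' Write a scan set to disk
#'
#' Serialises a scan set as a directory of plain-text files: the RF matrix and
#' reference waveforms as headerless CSV, a `meta.json` sidecar carrying all
#' geometry, seeds and ground truth, and a `ground_truth.csv` layer table.
#' Writing the same scan set twice produces byte-identical files.
#'
#' @param ss A `scan_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan_set <- function(ss, dir) {
  stopifnot(inherits(ss, "scan_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix <- function(x, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(
      format(x, digits = 17, trim = TRUE, scientific = TRUE),
      file = con, sep = ",", row.names = FALSE, col.names = FALSE,
      quote = FALSE, eol = "\n"
    )
  }
  write_matrix(ss$sample_scan$rf, file.path(dir, "rf.csv"))
  refs <- c("reference_no_tissue", "reference_with_tissue", "quartz_scan_for_incident")
  for (r in refs) {
    write_matrix(matrix(ss[[r]]$waveform, ncol = 1), file.path(dir, paste0(r, ".csv")))
  }
  scan <- ss$sample_scan
  meta <- list(
    sampling_rate = scan$sampling_rate,
    line_pitch = scan$line_pitch,
    scan_length = scan$scan_length,
    sound_speed_assumed = scan$sound_speed_assumed,
    depth_origin = scan$depth_origin,
    n_lines = nrow(scan$rf),
    n_samples = ncol(scan$rf),
    seed = ss$seed,
    references = lapply(setNames(refs, refs), function(r) {
      e <- ss[[r]]
      list(
        reflector_impedance = e$reflector_impedance,
        reflection_coefficient = e$reflection_coefficient,
        with_tissue = e$with_tissue,
        tissue_thickness = e$tissue_thickness
      )
    }),
    ground_truth = list(
      coupling_impedance = ss$ground_truth$coupling_impedance,
      coupling_sound_speed = ss$ground_truth$coupling_sound_speed,
      standoff = ss$ground_truth$standoff,
      substrate_impedance = ss$ground_truth$substrate_impedance,
      layers = lapply(ss$ground_truth$layers, unclass)
    )
  )
  writeLines(
    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"),
    file.path(dir, "meta.json")
  )
  readr::write_csv(tidy(ss$ground_truth), file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a scan set written by [write_scan_set()]
#'
#' @param dir Directory holding `rf.csv`, the reference CSVs and `meta.json`.
#' @return A `scan_set`.
#' @export
read_scan_set <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) abort(sprintf("No meta.json under '%s'.", dir))
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  rf <- as.matrix(utils::read.table(file.path(dir, "rf.csv"), sep = ","))
  dimnames(rf) <- NULL
  layers <- lapply(seq_len(nrow(meta$ground_truth$layers)), function(i) {
    l <- meta$ground_truth$layers[i, ]
    tissue_layer(l$name, l$thickness, l$impedance, l$attenuation,
                 l$backscatter_strength, l$scatterer_density, l$sound_speed)
  })
  phantom <- layered_phantom(
    layers,
    coupling_impedance = meta$ground_truth$coupling_impedance,
    coupling_sound_speed = meta$ground_truth$coupling_sound_speed,
    standoff = meta$ground_truth$standoff,
    substrate_impedance = meta$ground_truth$substrate_impedance
  )
  scan <- structure(
    list(
      rf = rf, sampling_rate = meta$sampling_rate, line_pitch = meta$line_pitch,
      scan_length = meta$scan_length,
      sound_speed_assumed = meta$sound_speed_assumed,
      depth_origin = meta$depth_origin, phantom = phantom, seed = meta$seed
    ),
    class = "bscan"
  )
  read_ref <- function(name) {
    w <- utils::read.table(file.path(dir, paste0(name, ".csv")), sep = ",")[[1]]
    info <- meta$references[[name]]
    structure(
      list(
        waveform = w, sampling_rate = meta$sampling_rate,
        reflector_impedance = info$reflector_impedance,
        reflection_coefficient = info$reflection_coefficient,
        with_tissue = isTRUE(info$with_tissue),
        tissue_thickness = info$tissue_thickness %||% NA_real_
      ),
      class = "reference_echo"
    )
  }
  scan_set(
    sample_scan = scan,
    reference_no_tissue = read_ref("reference_no_tissue"),
    reference_with_tissue = read_ref("reference_with_tissue"),
    quartz_scan_for_incident = read_ref("quartz_scan_for_incident"),
    ground_truth = phantom,
    seed = meta$seed
  )
}

#' Read / write TER series CSV
#'
#' The TER schema is one row per reading: `well_id`, `condition`, `time_min`,
#' `resistance_ohm`, `blank_resistance_ohm`, `membrane_area_cm2`.
#'
#' @param path CSV path.
#' @return `read_ter_csv()` returns the tibble; `write_ter_csv()` returns
#'   `path` invisibly.
#' @export
read_ter_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("well_id", "condition", "time_min", "resistance_ohm",
              "blank_resistance_ohm", "membrane_area_cm2")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("TER CSV is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  x
}

#' @rdname read_ter_csv
#' @param series TER tibble in the schema above.
#' @export
write_ter_csv <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}

#' Export an ROI mask
#'
#' Writes the mask either as a PNG-style 0/255 CSV grid or as run-length
#' encoded CSV (`line`, `start_sample`, `end_sample`).
#'
#' @param roi A `roi_mask`.
#' @param path Output path.
#' @param format `"grid"` (0/255 CSV) or `"rle"` (run-length CSV).
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(roi, path, format = c("grid", "rle")) {
  stopifnot(inherits(roi, "roi_mask"))
  format <- match.arg(format)
  if (format == "grid") {
    utils::write.table(roi$mask * 255L, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    runs <- purrr::map_dfr(seq_len(nrow(roi$mask)), function(li) {
      r <- rle(roi$mask[li, ])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      tibble(line = li, start_sample = starts[keep], end_sample = ends[keep])
    })
    readr::write_csv(runs, path)
  }
  invisible(path)
}
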