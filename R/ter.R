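#' Transepithelial electrical resistance
#'
#' `TER = (Res - Res_control) x Area`: the meter reading minus the
#' blank-insert reading, scaled by the insert membrane area. Linear in the
#' area and additive in resistance offsets.
#'
#' @param res Meter reading across the cell layer, Ohm (vectorised).
#' @param res_control Reading across a blank insert, Ohm.
#' @param area Insert membrane area, cm^2 (> 0; default 1.13, 12-well format).
#' @return TER in Ohm cm^2.
#' @examples
#' ter(800, 100, 1.0) # 700
#' @export
ter <- function(res, res_control, area = 1.13) {
  if (!is.numeric(area) || any(area <= 0)) abort("`area` must be > 0.")
  (res - res_control) * area
}

#' Is a monolayer ready as a small-intestine barrier model?
#'
#' TRUE when TER lies in the 500-1000 Ohm cm^2 window (inclusive on both
#' ends) that reflects an acceptable differentiated barrier.
#'
#' @param ter_value TER in Ohm cm^2 (vectorised).
#' @return Logical.
#' @export
barrier_ready <- function(ter_value) {
  ter_value >= 500 & ter_value <= 1000
}

# TER column from the raw series schema
series_ter <- function(series) {
  ter(series$resistance_ohm, series$blank_resistance_ohm,
      series$membrane_area_cm2)
}

#' Percentage TER drop of one well
#'
#' Baseline is the mean TER over the pre-insonation window
#' (`time < baseline_window`); the drop is
#' `100 x (baseline - min post-baseline TER) / baseline`. The recovery time is
#' the first time after the minimum at which TER is back within
#' `recovery_tolerance` of baseline (NA if it never recovers).
#'
#' @param series Tibble for a single well with columns `time_min`,
#'   `resistance_ohm`, `blank_resistance_ohm`, `membrane_area_cm2` and
#'   optionally `well_id`, `condition` (the schema written by
#'   [generate_ter_series()]).
#' @param baseline_window End of the baseline window in minutes; must contain
#'   at least one sample and precede the response.
#' @param recovery_tolerance Fractional distance from baseline counted as
#'   recovered (default 0.01).
#' @return One-row tibble with `well_id`, `condition`, `baseline_ter`,
#'   `min_ter`, `percent_drop`, `recovery_min` (on the series clock; NA if
#'   never recovered), `n_points`.
#' @export
percent_drop <- function(series, baseline_window, recovery_tolerance = 0.01) {
  if (nrow(series) < 2) abort("Need at least two samples.")
  t <- series$time_min
  y <- series_ter(series)
  base_idx <- which(t < baseline_window)
  if (length(base_idx) == 0) abort("Empty baseline window.")
  baseline <- mean(y[base_idx])
  post_idx <- which(t >= baseline_window)
  if (length(post_idx) == 0) abort("No post-baseline samples.")
  i_min <- post_idx[which.min(y[post_idx])]
  min_ter <- y[i_min]
  drop <- 100 * (baseline - min_ter) / baseline
  rec <- recovery_time(series, baseline, recovery_tolerance)
  tibble(
    well_id = series$well_id[1] %||% NA_character_,
    condition = series$condition[1] %||% NA_character_,
    baseline_ter = baseline, min_ter = min_ter,
    percent_drop = max(0, drop),
    recovery_min = rec, n_points = nrow(series)
  )
}

#' Time at which TER returns to baseline
#'
#' First time after the post-baseline minimum at which
#' `TER >= baseline x (1 - tolerance_fraction)`; NA if the series never
#' recovers.
#'
#' @param series Single-well tibble (see [percent_drop()]).
#' @param baseline Baseline TER, Ohm cm^2 (> 0).
#' @param tolerance_fraction Fractional recovery tolerance (default 0.01).
#' @return Recovery time in minutes (same clock as `time_min`), or NA.
#' @export
recovery_time <- function(series, baseline, tolerance_fraction = 0.01) {
  assert_scalar_number(baseline, "baseline", positive = TRUE)
  t <- series$time_min
  y <- series_ter(series)
  i_min <- which.min(y)
  after <- which(seq_along(y) > i_min & y >= baseline * (1 - tolerance_fraction))
  if (length(after) == 0) return(NA_real_)
  t[after[1]]
}

#' Per-condition summaries of TER response to insonation
#'
#' Computes the per-well percentage drop and recovery time, then averages
#' within condition. Conditions are returned in the fixed order `MB_only`,
#' `US_only`, `US_plus_MB`.
#'
#' @param all_series Tibble holding every well (schema of
#'   [generate_ter_series()]).
#' @param baseline_window End of the baseline window, minutes.
#' @param recovery_tolerance Fractional recovery tolerance.
#' @return A tibble of class `ter_summary`: one row per condition with
#'   `condition`, `n_wells`, `mean_percent_drop`, `sd_percent_drop`,
#'   `sem_percent_drop`, `mean_baseline_ter`, `mean_recovery_min`.
#' @export
summarize_conditions <- function(all_series, baseline_window = 5,
                                 recovery_tolerance = 0.01) {
  levels_known <- c("MB_only", "US_only", "US_plus_MB")
  if (!all(all_series$condition %in% levels_known)) {
    bad <- setdiff(unique(all_series$condition), levels_known)
    abort(sprintf("Unknown condition label(s): %s", paste(bad, collapse = ", ")))
  }
  per_well <- all_series |>
    dplyr::group_split(.data$condition, .data$well_id) |>
    purrr::map_dfr(percent_drop, baseline_window = baseline_window,
                   recovery_tolerance = recovery_tolerance)
  out <- per_well |>
    dplyr::mutate(condition = factor(.data$condition, levels = levels_known)) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      mean_percent_drop = mean(.data$percent_drop),
      sd_percent_drop = stats::sd(.data$percent_drop),
      sem_percent_drop = stats::sd(.data$percent_drop) / sqrt(dplyr::n()),
      mean_baseline_ter = mean(.data$baseline_ter),
      mean_recovery_min = mean(.data$recovery_min, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition) |>
    dplyr::mutate(condition = as.character(.data$condition))
  attr(out, "per_well") <- per_well
  class(out) <- c("ter_summary", class(out))
  out
}

#' @describeIn summarize_conditions Per-well drop/recovery tibble underlying
#'   the condition means.
#' @param x A `ter_summary`.
#' @param ... Unused.
#' @method tidy ter_summary
#' @export
tidy.ter_summary <- function(x, ...) attr(x, "per_well")
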