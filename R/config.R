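#' Analysis configuration
#'
#' Bundles every tunable used by the SHIMP analysis pipeline. Defaults are the
#' published operating point of the method: a head peak must rise at least
#' 100 deg/s above its basal velocity line and an eye peak 80 deg/s; exactly
#' one peak is kept per trace; the early-saccade time period (ESTP) is
#' head apex + 1.5 x head width + saccade width (all in samples); head
#' impulses are QC-flagged below 120 deg/s and counted as low-velocity below
#' 130 deg/s.
#'
#' @param head_min_prominence Minimum head-peak prominence (deg/s).
#' @param eye_min_prominence Minimum eye-peak prominence (deg/s), used for
#'   both the VOR pass and the inverted-trace saccade pass.
#' @param n_peaks Peaks kept per trace (the method uses 1).
#' @param latency_reference `"head_peak"` measures saccade latency from the
#'   head apex (as the method's response-latency definition); `"head_onset"`
#'   measures from the latest pre-apex sample at or below
#'   `onset_fraction * head prominence`.
#' @param onset_fraction Fraction of head prominence defining head onset.
#' @param low_velocity_threshold Head apex velocities strictly below this are
#'   counted as low-velocity impulses (deg/s).
#' @param qc_min_head_velocity Head apex velocities below this (strictly) set
#'   the `head_below_120` QC flag; the boundary itself passes (deg/s).
#' @param estp_head_width_factor Multiplier of the head width in the ESTP
#'   formula.
#' @param peak_selection Passed to [find_peaks()]: `"first"` (default) or
#'   `"max_prominence"` when several candidates pass the prominence filter.
#' @param early_reference What counts as the saccade's time of appearance in
#'   the ESTP comparison: its apex (`"apex"`, default) or its left
#'   half-prominence crossing (`"onset"`).
#'
#' @return A named list with class `shimp_config`.
#' @examples
#' cfg <- shimp_config(eye_min_prominence = 60)
#' cfg$eye_min_prominence
#' @export
shimp_config <- function(head_min_prominence = 100,
                         eye_min_prominence = 80,
                         n_peaks = 1L,
                         latency_reference = c("head_peak", "head_onset"),
                         onset_fraction = 0.10,
                         low_velocity_threshold = 130,
                         qc_min_head_velocity = 120,
                         estp_head_width_factor = 1.5,
                         peak_selection = c("first", "max_prominence"),
                         early_reference = c("apex", "onset")) {
  cfg <- list(
    head_min_prominence = head_min_prominence,
    eye_min_prominence = eye_min_prominence,
    n_peaks = as.integer(n_peaks),
    latency_reference = match.arg(latency_reference),
    onset_fraction = onset_fraction,
    low_velocity_threshold = low_velocity_threshold,
    qc_min_head_velocity = qc_min_head_velocity,
    estp_head_width_factor = estp_head_width_factor,
    peak_selection = match.arg(peak_selection),
    early_reference = match.arg(early_reference)
  )
  stopifnot(
    cfg$head_min_prominence > 0, cfg$eye_min_prominence > 0,
    cfg$n_peaks >= 1L, cfg$onset_fraction > 0, cfg$onset_fraction < 1,
    cfg$low_velocity_threshold > 0, cfg$qc_min_head_velocity > 0,
    cfg$estp_head_width_factor > 0
  )
  structure(cfg, class = "shimp_config")
}

#' @export
print.shimp_config <- function(x, ...) {
  cat("SHIMP analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_shimp_config <- function(x) {
  if (inherits(x, "shimp_config")) {
    return(x)
  }
  do.call(shimp_config, as.list(x))
}
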