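#' Normalize impulse direction
#'
#' vHIT head impulses are delivered to the left and to the right; in the
#' device convention a leftward impulse has a negative head-velocity lobe.
#' Analysis always works on a positive head lobe, so when the extreme head
#' velocity (largest absolute value) is negative, both the head and the eye
#' trace are negated. The stored eye trace keeps the device convention: the
#' slow-phase (VOR) lobe is aligned with the head, the anticompensatory
#' saccade lobe is negative.
#'
#' Applying the operation twice equals applying it once.
#'
#' @param traces Long-format trace tibble with columns `impulse_id`, `side`,
#'   `sample_index`, `head_velocity_degps`, `eye_velocity_degps` (as returned
#'   by [read_shimp_csv()], [read_shimp_xml()] or [simulate_test()]).
#' @return The same tibble with normalized velocities and an added `sign`
#'   column (+1 or -1, the factor that was applied per impulse).
#' @export
normalize_direction <- function(traces) {
  check_traces(traces)
  traces |>
    dplyr::group_by(.data$impulse_id) |>
    dplyr::mutate(sign = impulse_sign(.data$head_velocity_degps)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      head_velocity_degps = .data$head_velocity_degps * .data$sign,
      eye_velocity_degps = .data$eye_velocity_degps * .data$sign
    )
}

impulse_sign <- function(head) {
  if (all(head == 0)) {
    stop("all-zero head trace: direction is undefined", call. = FALSE)
  }
  unname(sign(head[which.max(abs(head))]))
}

#' Detect the head-impulse peak
#'
#' Single-pass peak detection on the (direction-normalized) head velocity
#' trace with the head prominence threshold (default 100 deg/s).
#'
#' @param head Numeric head-velocity trace (deg/s), positive-lobe orientation.
#' @param config An [shimp_config()] object.
#' @return One-row peak tibble (see [find_peaks()]) or zero rows when no peak
#'   passes the prominence filter.
#' @export
detect_head_peak <- function(head, config = shimp_config()) {
  config <- as_shimp_config(config)
  find_peaks(head, config$head_min_prominence, config$n_peaks,
    selection = config$peak_selection
  )
}

#' Detect the VOR peak (first eye pass)
#'
#' Peak detection on the eye trace in its stored orientation (slow phase
#' aligned with the head), eye prominence threshold (default 80 deg/s). This
#' is the compensatory slow-phase response; in vestibular loss it falls below
#' threshold and no peak is returned.
#'
#' @param eye Numeric eye-velocity trace (deg/s), stored orientation.
#' @inheritParams detect_head_peak
#' @return One-row peak tibble or zero rows.
#' @export
detect_vor_peak <- function(eye, config = shimp_config()) {
  config <- as_shimp_config(config)
  find_peaks(eye, config$eye_min_prominence, config$n_peaks,
    selection = config$peak_selection
  )
}

#' Detect the SHIMP saccade (second eye pass, inverted trace)
#'
#' The anticompensatory SHIMP saccade opposes the slow-phase response, so it
#' is a trough in the stored eye trace. The second pass therefore runs peak
#' detection on the negated eye trace with the same eye prominence threshold.
#' Returned index/width refer to the original time axis; `velocity` and
#' `prominence` are the (positive) magnitudes measured on the negated trace.
#'
#' @inheritParams detect_vor_peak
#' @return One-row peak tibble or zero rows.
#' @export
detect_shimp_saccade <- function(eye, config = shimp_config()) {
  config <- as_shimp_config(config)
  find_peaks(-eye, config$eye_min_prominence, config$n_peaks,
    selection = config$peak_selection
  )
}

#' Early saccade time period (ESTP)
#'
#' The width-based bound that separates early from not-early SHIMP saccades:
#' `ESTP = Hpt + factor * Hw + Sw` with `Hpt` the head apex position, `Hw`
#' the head width at half prominence, `Sw` the saccade width at half
#' prominence, all in samples on the shared time axis, and `factor` 1.5 by
#' default. Being width-based, the bound does not depend on where the head
#' velocity recrosses zero, which makes it robust to post-impulse overshoot.
#'
#' @param head_peak,saccade_peak One-row peak tibbles from
#'   [detect_head_peak()] / [detect_shimp_saccade()].
#' @inheritParams detect_head_peak
#' @return ESTP in samples (fractional).
#' @examples
#' h <- tibble::tibble(index = 40, width = 20)
#' s <- tibble::tibble(index = 70, width = 8)
#' compute_estp(h, s) # 40 + 1.5 * 20 + 8 = 78
#' @export
compute_estp <- function(head_peak, saccade_peak, config = shimp_config()) {
  config <- as_shimp_config(config)
  stopifnot(nrow(head_peak) == 1L, nrow(saccade_peak) == 1L)
  head_peak$index + config$estp_head_width_factor * head_peak$width +
    saccade_peak$width
}

#' Classify a saccade as early or not early
#'
#' A SHIMP saccade is early when its time of appearance is strictly less than
#' the ESTP bound; the comparison is done in samples, never in derived
#' milliseconds. A tie resolves to not-early. The time of appearance is the
#' saccade apex by default (`early_reference = "apex"`), or its left
#' half-prominence crossing with `early_reference = "onset"`.
#'
#' @param saccade_peak One-row peak tibble for the saccade.
#' @param estp_samples ESTP bound from [compute_estp()].
#' @inheritParams detect_head_peak
#' @return Logical scalar.
#' @export
classify_early <- function(saccade_peak, estp_samples, config = shimp_config()) {
  config <- as_shimp_config(config)
  appearance <- switch(config$early_reference,
    apex = saccade_peak$index,
    onset = saccade_peak$left_crossing
  )
  appearance < estp_samples
}

#' Saccade latency
#'
#' Latency of the SHIMP saccade relative to the head movement. The default
#' reference is the head apex (latency = saccade apex - head apex, the
#' method's response-latency definition); with
#' `latency_reference = "head_onset"` the reference is the latest sample
#' before the head apex whose value is at or below
#' `onset_fraction * head prominence`. Milliseconds are derived exactly as
#' `samples * 1000 / rate_hz`.
#'
#' A non-positive latency (saccade at or before the reference) is reported,
#' not suppressed; callers flag it as irregular.
#'
#' @inheritParams compute_estp
#' @param head Numeric head trace (needed for the onset reference).
#' @param rate_hz Sampling rate in Hz.
#' @return List with `latency_samples`, `latency_ms` and `reference_index`.
#' @export
compute_latency <- function(head_peak, saccade_peak, head,
                            config = shimp_config(), rate_hz = 250) {
  config <- as_shimp_config(config)
  stopifnot(nrow(head_peak) == 1L, nrow(saccade_peak) == 1L, rate_hz > 0)
  ref <- head_peak$index
  if (config$latency_reference == "head_onset") {
    thr <- config$onset_fraction * head_peak$prominence
    before <- which(head[seq_len(head_peak$index)] <= thr) # 1-based, pre-apex
    ref <- if (length(before) == 0L) 0 else max(before) - 1L
  }
  lat <- saccade_peak$index - ref
  list(
    latency_samples = as.numeric(lat),
    latency_ms = as.numeric(lat) * 1000 / rate_hz,
    reference_index = as.numeric(ref)
  )
}

#' Analyze one head impulse
#'
#' Runs the full per-impulse pipeline on a pair of velocity vectors:
#' direction normalization, head-peak detection, the dual eye pass (VOR peak
#' on the stored trace, SHIMP saccade on the inverted trace), ESTP
#' computation, early classification, latency, and QC flags. At most one
#' saccade is detected and classified per impulse. The analysis never errors
#' on signal content: missing responses propagate as `NA` fields with the
#' corresponding QC flag set.
#'
#' A saccade is only reported when a head peak exists (latency and ESTP need
#' the reference); an all-zero head trace yields a fully flagged row.
#'
#' @param head,eye Numeric velocity vectors (deg/s) of equal length.
#' @inheritParams compute_latency
#' @param impulse_id,side Labels copied into the output row.
#' @return One-row tibble; see [analyze_impulses()] for the columns.
#' @export
analyze_impulse <- function(head, eye, config = shimp_config(), rate_hz = 250,
                            impulse_id = "impulse", side = "unknown") {
  config <- as_shimp_config(config)
  validate_trace(head)
  validate_trace(eye)
  if (length(head) != length(eye)) {
    stop("head and eye traces must have equal length", call. = FALSE)
  }
  stopifnot(rate_hz > 0)
  ms <- 1000 / rate_hz

  out <- tibble::tibble(
    impulse_id = impulse_id, side = side, sign = NA_real_,
    head_index = NA_integer_, head_velocity = NA_real_,
    head_prominence = NA_real_, head_width = NA_real_, head_width_ms = NA_real_,
    vor_index = NA_integer_, vor_velocity = NA_real_, vor_prominence = NA_real_,
    saccade_index = NA_integer_, saccade_velocity = NA_real_,
    saccade_width = NA_real_, saccade_width_ms = NA_real_,
    saccade_onset = NA_real_,
    latency_samples = NA_real_, latency_ms = NA_real_,
    estp_samples = NA_real_, early = NA,
    qc_no_head_peak = FALSE, qc_no_saccade = FALSE, qc_head_below_120 = FALSE,
    qc_width_clamped = FALSE, qc_irregular = FALSE
  )

  if (all(head == 0)) {
    out$qc_no_head_peak <- TRUE
    out$qc_no_saccade <- TRUE
    return(out)
  }
  s <- impulse_sign(head)
  out$sign <- s
  head <- head * s
  eye <- eye * s

  hp <- detect_head_peak(head, config)
  if (nrow(hp) == 1L) {
    out$head_index <- as.integer(hp$index)
    out$head_velocity <- hp$velocity
    out$head_prominence <- hp$prominence
    out$head_width <- hp$width
    out$head_width_ms <- hp$width * ms
    out$qc_width_clamped <- out$qc_width_clamped || hp$width_clamped
    out$qc_head_below_120 <- hp$velocity < config$qc_min_head_velocity
  } else {
    out$qc_no_head_peak <- TRUE
  }

  vp <- detect_vor_peak(eye, config)
  if (nrow(vp) == 1L) {
    out$vor_index <- as.integer(vp$index)
    out$vor_velocity <- vp$velocity
    out$vor_prominence <- vp$prominence
  }

  sp <- detect_shimp_saccade(eye, config)
  if (nrow(hp) == 1L && nrow(sp) == 1L) {
    out$saccade_index <- as.integer(sp$index)
    out$saccade_velocity <- sp$prominence
    out$saccade_width <- sp$width
    out$saccade_width_ms <- sp$width * ms
    out$saccade_onset <- sp$left_crossing
    out$qc_width_clamped <- out$qc_width_clamped || sp$width_clamped
    out$estp_samples <- compute_estp(hp, sp, config)
    out$early <- classify_early(sp, out$estp_samples, config)
    lat <- compute_latency(hp, sp, head, config, rate_hz)
    out$latency_samples <- lat$latency_samples
    out$latency_ms <- lat$latency_ms
    out$qc_irregular <- lat$latency_samples <= 0
  } else {
    out$qc_no_saccade <- TRUE
  }
  out
}

#' Analyze a SHIMP test (all impulses)
#'
#' Data-frame-first front end: takes the long-format trace tibble of a whole
#' test and returns one analysis row per impulse. Impulses are flagged, never
#' dropped — exclusion on QC flags (for example `qc_head_below_120`) is the
#' caller's choice.
#'
#' @inheritParams normalize_direction
#' @inheritParams detect_head_peak
#' @param rate_hz Sampling rate in Hz; defaults to the `rate_hz` attribute of
#'   `traces` (set by the readers and the simulator), else 250.
#' @return A tibble of class `shimp_analysis` with one row per impulse:
#'   impulse labels, the applied direction `sign`, head peak fields
#'   (`head_index`, `head_velocity`, `head_prominence`, `head_width`,
#'   `head_width_ms`), VOR peak fields, saccade fields (`saccade_index`,
#'   `saccade_velocity`, `saccade_width`, `saccade_width_ms`,
#'   `saccade_onset`), `latency_samples`/`latency_ms`, `estp_samples`,
#'   `early`, and logical `qc_*` flags. Indices are 0-based sample positions.
#'   [glance()] on the result gives the per-test summary.
#' @examples
#' sim <- simulate_test(3, preset = "predictable", seed = 1)
#' analyze_impulses(sim$traces)
#' @export
analyze_impulses <- function(traces, config = shimp_config(), rate_hz = NULL) {
  check_traces(traces)
  config <- as_shimp_config(config)
  if (is.null(rate_hz)) rate_hz <- attr(traces, "rate_hz") %||% 250

  res <- traces |>
    dplyr::group_by(.data$impulse_id) |>
    dplyr::group_map(function(g, key) {
      g <- dplyr::arrange(g, .data$sample_index)
      analyze_impulse(
        g$head_velocity_degps, g$eye_velocity_degps,
        config = config, rate_hz = rate_hz,
        impulse_id = key$impulse_id,
        side = as.character(g$side[1])
      )
    }) |>
    dplyr::bind_rows()
  # restore input impulse order (group_map sorts by key)
  res <- res[match(unique(traces$impulse_id), res$impulse_id), ]
  structure(res,
    class = c("shimp_analysis", class(res)),
    rate_hz = rate_hz, config = config
  )
}

check_traces <- function(traces) {
  needed <- c(
    "impulse_id", "side", "sample_index",
    "head_velocity_degps", "eye_velocity_degps"
  )
  missing <- setdiff(needed, names(traces))
  if (length(missing) > 0L) {
    stop("trace table is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(traces)
}

#' @export
print.shimp_analysis <- function(x, ...) {
  cat(sprintf(
    "SHIMP analysis: %d impulses at %g Hz (%d with saccade, %d early)\n",
    nrow(x), attr(x, "rate_hz"),
    sum(!is.na(x$saccade_index)), sum(x$early, na.rm = TRUE)
  ))
  NextMethod()
}
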