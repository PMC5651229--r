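fwhm_factor <- 2 * sqrt(2 * log(2)) # FWHM of a Gaussian lobe = factor * sigma

#' Simulation parameters for one SHIMP impulse
#'
#' The generator's model of one SHIMP trial: a bell-shaped (Gaussian) head
#' velocity lobe with an optional opposite-direction overshoot lobe after it,
#' an eye trace made of a gain-scaled slow-phase copy of the main head lobe
#' minus an anticompensatory saccade lobe at a configurable latency, plus
#' additive Gaussian noise on the eye channel. All lobe timing is in samples
#' at `rate_hz`; the saccade centre is snapped to the sample grid so ground
#' truth lives on the same grid the detector reports on.
#'
#' The overshoot lobe has compact support (truncated at 3 sigma) and must lie
#' entirely after the main lobe's right half-prominence crossing; this is the
#' configuration against which the width-based timing quantities are provably
#' invariant.
#'
#' Defaults describe a brisk, clinically ordinary impulse: 200 deg/s head
#' apex (comfortably above the 120 deg/s QC floor), ~100 ms head-lobe FWHM,
#' VOR gain 0.9, 250 deg/s saccade of ~26 ms FWHM, 5 deg/s eye noise.
#'
#' @param rate_hz Sampling rate (Hz).
#' @param n_samples Trace length in samples (250 = 1 s at 250 Hz).
#' @param head_peak_velocity Head apex velocity (deg/s).
#' @param head_sigma Gaussian scale of the head lobe (samples); default gives
#'   a 25-sample (100 ms) FWHM.
#' @param head_peak_time Head apex position (samples, 0-based integer).
#' @param overshoot_amplitude Amplitude of the post-impulse overshoot lobe
#'   (deg/s, >= 0; 0 disables it).
#' @param overshoot_delay Delay of the overshoot centre beyond
#'   `head_peak_time + 3 * head_sigma` (samples).
#' @param overshoot_sigma Gaussian scale of the overshoot lobe (samples).
#' @param vor_gain Slow-phase gain (eye/head, 0 in complete loss).
#' @param saccade_amplitude Saccade lobe amplitude (deg/s).
#' @param saccade_latency_ms Saccade apex latency after the head apex (ms).
#' @param saccade_sigma Gaussian scale of the saccade lobe (samples); default
#'   gives ~26 ms FWHM.
#' @param noise_sd SD of additive Gaussian noise on the eye channel (deg/s).
#' @return A named list of class `shimp_sim_spec`.
#' @export
simulate_spec <- function(rate_hz = 250,
                          n_samples = 250L,
                          head_peak_velocity = 200,
                          head_sigma = 25 / fwhm_factor,
                          head_peak_time = 40L,
                          overshoot_amplitude = 0,
                          overshoot_delay = 15,
                          overshoot_sigma = 6,
                          vor_gain = 0.9,
                          saccade_amplitude = 250,
                          saccade_latency_ms = 100,
                          saccade_sigma = 2.8,
                          noise_sd = 5) {
  spec <- list(
    rate_hz = rate_hz, n_samples = as.integer(n_samples),
    head_peak_velocity = head_peak_velocity, head_sigma = head_sigma,
    head_peak_time = as.integer(head_peak_time),
    overshoot_amplitude = overshoot_amplitude,
    overshoot_delay = overshoot_delay, overshoot_sigma = overshoot_sigma,
    vor_gain = vor_gain, saccade_amplitude = saccade_amplitude,
    saccade_latency_ms = saccade_latency_ms, saccade_sigma = saccade_sigma,
    noise_sd = noise_sd
  )
  stopifnot(
    spec$rate_hz > 0, spec$n_samples >= 3L,
    spec$head_peak_velocity > 0, spec$head_sigma > 0,
    spec$head_peak_time >= 0, spec$overshoot_amplitude >= 0,
    spec$overshoot_sigma > 0, spec$vor_gain >= 0,
    spec$saccade_amplitude >= 0, spec$saccade_sigma > 0, spec$noise_sd >= 0
  )
  if (spec$overshoot_amplitude > 0) {
    support_start <- spec$head_peak_time + 3 * spec$head_sigma +
      spec$overshoot_delay - 3 * spec$overshoot_sigma
    right_crossing <- spec$head_peak_time + sqrt(2 * log(2)) * spec$head_sigma
    if (support_start <= right_crossing) {
      stop("overshoot lobe must lie entirely after the head lobe's right ",
        "half-prominence crossing; increase overshoot_delay or decrease ",
        "overshoot_sigma",
        call. = FALSE
      )
    }
  }
  structure(spec, class = "shimp_sim_spec")
}

#' Simulate one SHIMP impulse with ground truth
#'
#' Generates one paired head/eye velocity trace from a [simulate_spec()] and
#' returns it together with the ground truth the generator used: the true
#' head apex position and width (closed-form Gaussian FWHM), true saccade
#' apex, true latency, and the true early flag computed by applying the ESTP
#' rule (`apex < Hpt + 1.5 Hw + Sw`) to the true quantities.
#'
#' Left-sided impulses are stored in device convention (negative head lobe);
#' ground truth always refers to the normalized (positive-lobe) orientation.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec A [simulate_spec()].
#' @param seed Optional integer seed (RNG state is restored afterwards); when
#'   `NULL` the current RNG stream is used.
#' @param impulse_id,side Labels for the generated impulse (`side` one of
#'   `"right"`, `"left"`).
#' @return List with `traces` (long tibble: `impulse_id`, `side`,
#'   `sample_index`, `head_velocity_degps`, `eye_velocity_degps`) and `truth`
#'   (one-row tibble of `true_*` quantities).
#' @examples
#' imp <- simulate_impulse(simulate_spec(noise_sd = 0), seed = 1)
#' imp$truth
#' @export
simulate_impulse <- function(spec = simulate_spec(), seed = NULL,
                             impulse_id = "imp001", side = c("right", "left")) {
  stopifnot(inherits(spec, "shimp_sim_spec"))
  side <- match.arg(side)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      simulate_impulse(spec, NULL, impulse_id, side)
    ))
  }

  t <- seq_len(spec$n_samples) - 1 # 0-based sample positions
  t0 <- spec$head_peak_time
  sacc_apex <- t0 + as.integer(round(spec$saccade_latency_ms * spec$rate_hz / 1000))
  if (sacc_apex >= spec$n_samples) {
    stop("saccade apex falls beyond the trace (", sacc_apex, " >= ",
      spec$n_samples, " samples); shorten saccade_latency_ms or lengthen ",
      "n_samples",
      call. = FALSE
    )
  }

  gauss <- function(center, sigma) exp(-(t - center)^2 / (2 * sigma^2))
  head_main <- spec$head_peak_velocity * gauss(t0, spec$head_sigma)
  head <- head_main
  if (spec$overshoot_amplitude > 0) {
    oc <- t0 + 3 * spec$head_sigma + spec$overshoot_delay
    lobe <- spec$overshoot_amplitude * gauss(oc, spec$overshoot_sigma)
    lobe[abs(t - oc) > 3 * spec$overshoot_sigma] <- 0 # compact support
    head <- head - lobe
  }
  eye <- spec$vor_gain * head_main -
    spec$saccade_amplitude * gauss(sacc_apex, spec$saccade_sigma)
  if (spec$noise_sd > 0) {
    eye <- eye + stats::rnorm(spec$n_samples, 0, spec$noise_sd)
  }
  s <- if (side == "left") -1 else 1

  true_head_width <- fwhm_factor * spec$head_sigma
  true_saccade_width <- fwhm_factor * spec$saccade_sigma
  true_estp <- t0 + 1.5 * true_head_width + true_saccade_width
  list(
    traces = tibble::tibble(
      impulse_id = impulse_id, side = side, sample_index = as.integer(t),
      head_velocity_degps = s * head, eye_velocity_degps = s * eye
    ),
    truth = tibble::tibble(
      impulse_id = impulse_id, side = side,
      true_head_apex = as.integer(t0),
      true_head_velocity = spec$head_peak_velocity,
      true_head_width = true_head_width,
      true_saccade_apex = as.integer(sacc_apex),
      true_saccade_width = true_saccade_width,
      true_latency_ms = (sacc_apex - t0) * 1000 / spec$rate_hz,
      true_estp = true_estp,
      true_early = sacc_apex < true_estp
    )
  )
}

#' Protocol latency presets
#'
#' First-saccade latency distributions of the three SHIMP delivery protocols,
#' as Normal(mean, sd) in milliseconds: predictable 112.8 +/- 56.96,
#' less predictable 152.04 +/- 58.00, unpredictable 178.32 +/- 46.04. The
#' plus/minus values are treated as SDs for sampling (a documented modelling
#' assumption). At sampling time draws are truncated (clamped) to
#' [20 ms, trace end - 3 saccade sigma].
#'
#' @param name One of `"predictable"`, `"less_predictable"`,
#'   `"unpredictable"`.
#' @return List with `name`, `latency_mean_ms`, `latency_sd_ms`.
#' @examples
#' protocol_preset("predictable")$latency_mean_ms
#' @export
protocol_preset <- function(name) {
  presets <- list(
    predictable = list(latency_mean_ms = 112.8, latency_sd_ms = 56.96),
    less_predictable = list(latency_mean_ms = 152.04, latency_sd_ms = 58.00),
    unpredictable = list(latency_mean_ms = 178.32, latency_sd_ms = 46.04)
  )
  if (length(name) != 1L || !name %in% names(presets)) {
    stop("unknown preset ", deparse(name), "; valid presets: ",
      paste(names(presets), collapse = ", "),
      call. = FALSE
    )
  }
  c(list(name = name), presets[[name]])
}

#' Simulate a whole SHIMP test
#'
#' Draws per-impulse saccade latencies from a protocol preset (or keeps the
#' spec's fixed latency when `preset` is `NULL`), alternates impulse sides
#' right/left, and stacks the generated impulses into one long trace tibble
#' plus a ground-truth tibble. Deterministic under `seed`.
#'
#' Latency draws are clamped to `[20 ms, trace end - 3 saccade sigma]` so
#' every saccade lobe fits inside the trace.
#'
#' @param n_impulses Number of impulses (>= 1).
#' @param preset Preset name for [protocol_preset()], or `NULL` for the fixed
#'   `spec$saccade_latency_ms`.
#' @param spec Base [simulate_spec()]; per-impulse latency overrides its
#'   `saccade_latency_ms`.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param test_id Label attached to the output.
#' @return List with `traces` (long tibble carrying `rate_hz`, `protocol` and
#'   `test_id` attributes, ready for [analyze_impulses()]) and `truth` (one
#'   row per impulse).
#' @examples
#' sim <- simulate_test(5, preset = "unpredictable", seed = 42)
#' dplyr::count(sim$traces, impulse_id)
#' @export
simulate_test <- function(n_impulses, preset = "predictable",
                          spec = simulate_spec(), seed = NULL,
                          test_id = "simulated_test") {
  stopifnot(inherits(spec, "shimp_sim_spec"), n_impulses >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      simulate_test(n_impulses, preset, spec, NULL, test_id)
    ))
  }
  n_impulses <- as.integer(n_impulses)
  ms_per_sample <- 1000 / spec$rate_hz
  lat_max <- (spec$n_samples - 1) * ms_per_sample -
    (spec$head_peak_time * ms_per_sample + 3 * spec$saccade_sigma * ms_per_sample)
  if (is.null(preset)) {
    latencies <- rep(spec$saccade_latency_ms, n_impulses)
    protocol <- NA_character_
  } else {
    p <- protocol_preset(preset)
    latencies <- stats::rnorm(n_impulses, p$latency_mean_ms, p$latency_sd_ms)
    protocol <- p$name
  }
  latencies <- pmin(pmax(latencies, 20), lat_max)
  sides <- rep_len(c("right", "left"), n_impulses)

  sims <- purrr::map(seq_len(n_impulses), function(i) {
    spec_i <- spec
    spec_i$saccade_latency_ms <- latencies[i]
    simulate_impulse(spec_i,
      seed = NULL,
      impulse_id = sprintf("imp%03d", i), side = sides[i]
    )
  })
  traces <- dplyr::bind_rows(purrr::map(sims, "traces"))
  attr(traces, "rate_hz") <- spec$rate_hz
  attr(traces, "protocol") <- protocol
  attr(traces, "test_id") <- test_id
  list(
    traces = traces,
    truth = dplyr::bind_rows(purrr::map(sims, "truth"))
  )
}
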