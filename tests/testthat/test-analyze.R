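sim_traces <- function(..., seed = 1, side = "right") {
  simulate_impulse(simulate_spec(...), seed = seed, side = side)
}

test_that("normalize_direction flips leftward impulses and is idempotent", {
  imp <- sim_traces(noise_sd = 0, side = "left")$traces
  expect_lt(min(imp$head_velocity_degps), -100) # stored device convention
  norm <- normalize_direction(imp)
  expect_equal(unique(norm$sign), -1)
  expect_gt(max(norm$head_velocity_degps), 100)
  norm2 <- normalize_direction(norm[names(imp)])
  expect_equal(unique(norm2$sign), 1)
  expect_equal(norm2$head_velocity_degps, norm$head_velocity_degps)

  right <- sim_traces(noise_sd = 0, side = "right")$traces
  norm_r <- normalize_direction(right)
  expect_equal(unique(norm_r$sign), 1)
  expect_equal(norm_r$head_velocity_degps, right$head_velocity_degps)

  zero <- tibble::tibble(
    impulse_id = "z", side = "unknown", sample_index = 0:2,
    head_velocity_degps = 0, eye_velocity_degps = c(0, 1, 0)
  )
  expect_error(normalize_direction(zero), "all-zero head")
})

test_that("head, VOR and saccade detection recover simulator ground truth", {
  sim <- sim_traces(noise_sd = 0)
  head <- sim$traces$head_velocity_degps
  eye <- sim$traces$eye_velocity_degps

  hp <- detect_head_peak(head)
  expect_equal(hp$index, 40L)
  expect_equal(hp$velocity, 200, tolerance = 1e-6)

  vp <- detect_vor_peak(eye)
  expect_equal(vp$index, 40L, tolerance = 1) # VOR apex in the head-lobe region
  expect_equal(vp$prominence, 180, tolerance = 0.05)

  sp <- detect_shimp_saccade(eye)
  expect_equal(sp$index, sim$truth$true_saccade_apex)

  # below-threshold responses are absent
  expect_equal(nrow(detect_head_peak(0.45 * head)), 0L) # apex 90 < 100
  low_gain <- sim_traces(noise_sd = 0, vor_gain = 0.3, saccade_amplitude = 0)
  expect_equal(nrow(detect_vor_peak(low_gain$traces$eye_velocity_degps)), 0L)
  small_sacc <- sim_traces(noise_sd = 0, saccade_amplitude = 50, vor_gain = 0)
  expect_equal(nrow(detect_shimp_saccade(small_sacc$traces$eye_velocity_degps)), 0L)

  # dual-pass symmetry: saccade pass is the VOR pass on the negated trace
  expect_equal(detect_shimp_saccade(eye), detect_vor_peak(-eye))
})

test_that("ESTP is Hpt + 1.5 Hw + Sw and early uses a strict comparison", {
  h <- tibble::tibble(index = 40, width = 20)
  s <- tibble::tibble(index = 70, width = 8)
  expect_equal(compute_estp(h, s), 78)
  # degenerate limit and linearity in the head width
  expect_equal(compute_estp(tibble::tibble(index = 40, width = 0), s), 48)
  h2 <- tibble::tibble(index = 40, width = 40)
  expect_equal(compute_estp(h2, s) - compute_estp(h, s), 1.5 * 20)

  expect_true(classify_early(tibble::tibble(index = 70, left_crossing = 68), 78))
  expect_false(classify_early(tibble::tibble(index = 78, left_crossing = 76), 78)) # tie
  # onset reference uses the left half-prominence crossing instead
  cfg <- shimp_config(early_reference = "onset")
  expect_true(classify_early(tibble::tibble(index = 79, left_crossing = 77.5), 78, cfg))
})

test_that("latency is Sp - Hp in samples, converted exactly to ms", {
  hp <- tibble::tibble(index = 38L, prominence = 200)
  sp <- tibble::tibble(index = 55L)
  head <- c(rep(0, 20), 200 * exp(-((20:99) - 38)^2 / 50))
  lat <- compute_latency(hp, sp, head, rate_hz = 250)
  expect_equal(lat$latency_samples, 17)
  expect_equal(lat$latency_ms, 68) # 4 ms per sample at 250 Hz
  expect_equal(compute_latency(hp, tibble::tibble(index = 38L), head)$latency_ms, 0)

  # onset reference precedes the apex, so onset latency >= peak latency
  cfg <- shimp_config(latency_reference = "head_onset")
  lat_on <- compute_latency(hp, sp, head, cfg, rate_hz = 250)
  expect_lt(lat_on$reference_index, 38)
  expect_gte(lat_on$latency_ms, lat$latency_ms)
})

test_that("analyze_impulse runs the full chain and flags missing responses", {
  sim <- sim_traces(noise_sd = 0)
  a <- analyze_impulse(
    sim$traces$head_velocity_degps, sim$traces$eye_velocity_degps
  )
  expect_equal(a$head_index, 40L)
  expect_equal(a$saccade_index, sim$truth$true_saccade_apex)
  expect_equal(a$latency_ms, sim$truth$true_latency_ms)
  expect_equal(a$early, sim$truth$true_early)
  expect_false(any(unlist(a[startsWith(names(a), "qc_")])))

  # early case with hand-computed ESTP
  early <- sim_traces(noise_sd = 0, saccade_latency_ms = 50)
  ae <- analyze_impulse(
    early$traces$head_velocity_degps, early$traces$eye_velocity_degps
  )
  expect_true(ae$early)
  expect_equal(
    ae$estp_samples,
    ae$head_index + 1.5 * ae$head_width + ae$saccade_width
  )

  # flat eye trace: no saccade, flagged, nothing else crashes
  flat <- analyze_impulse(sim$traces$head_velocity_degps, rep(0, 250))
  expect_true(flat$qc_no_saccade)
  expect_true(is.na(flat$saccade_index))
  expect_true(is.na(flat$early))

  # all-zero head trace is flagged rather than raising
  zz <- analyze_impulse(rep(0, 250), sim$traces$eye_velocity_degps)
  expect_true(zz$qc_no_head_peak)
})

test_that("QC thresholds: 120 deg/s passes, below does not; precedence", {
  eye <- c(0, 0, -200, 0, 0)
  a_lo <- analyze_impulse(c(0, 0, 119.9, 0, 0), eye)
  expect_true(a_lo$qc_head_below_120)
  a_ok <- analyze_impulse(c(0, 0, 120, 0, 0), eye) # boundary is inclusive
  expect_false(a_ok$qc_head_below_120)
  a_none <- analyze_impulse(c(0, 0, 90, 0, 0), eye)
  expect_true(a_none$qc_no_head_peak)
  expect_false(a_none$qc_head_below_120) # not evaluated without a head peak
})

test_that("direction symmetry: negated record gives the same analysis", {
  sim <- sim_traces(noise_sd = 5, seed = 7)
  h <- sim$traces$head_velocity_degps
  e <- sim$traces$eye_velocity_degps
  a1 <- analyze_impulse(h, e)
  a2 <- analyze_impulse(-h, -e)
  expect_equal(a1$sign, 1)
  expect_equal(a2$sign, -1)
  cols <- setdiff(names(a1), "sign")
  expect_equal(a1[cols], a2[cols])
})

test_that("post-lobe overshoot changes no width-based timing quantity", {
  for (seed in 1:5) {
    lat <- 60 + 20 * seed
    base <- simulate_impulse(
      simulate_spec(noise_sd = 5, saccade_latency_ms = lat),
      seed = seed
    )
    over <- simulate_impulse(
      simulate_spec(
        noise_sd = 5, saccade_latency_ms = lat,
        overshoot_amplitude = 80, overshoot_delay = 20, overshoot_sigma = 6
      ),
      seed = seed
    )
    a1 <- analyze_impulse(
      base$traces$head_velocity_degps, base$traces$eye_velocity_degps
    )
    a2 <- analyze_impulse(
      over$traces$head_velocity_degps, over$traces$eye_velocity_degps
    )
    expect_identical(a1$head_index, a2$head_index)
    expect_identical(a1$head_width, a2$head_width)
    expect_identical(a1$estp_samples, a2$estp_samples)
    expect_identical(a1$early, a2$early)
  }
})

test_that("analyze_impulses preserves impulse order and exposes glance()", {
  sim <- simulate_test(6, preset = "unpredictable", seed = 3)
  a <- analyze_impulses(sim$traces)
  expect_s3_class(a, "shimp_analysis")
  expect_equal(a$impulse_id, sprintf("imp%03d", 1:6))
  expect_equal(nrow(a), 6)
  expect_true(all(!is.na(a$saccade_index)))
  g <- glance(a)
  expect_s3_class(g, "shimp_summary")
  expect_equal(g$n_impulses, 6)
  expect_identical(tidy(a)$latency_ms, a$latency_ms)
})
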