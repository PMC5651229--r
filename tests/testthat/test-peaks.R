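test_that("local maxima: triangles, plateaus, monotone traces", {
  expect_identical(find_local_maxima(c(0, 1, 0)), 1L)
  expect_identical(find_local_maxima(c(0, 2, 2, 2, 0)), 1L) # plateau -> first
  expect_identical(find_local_maxima(c(3, 2, 1)), integer())
  expect_identical(find_local_maxima(c(1, 1, 1)), integer())
  # endpoints never candidates, even when highest
  expect_identical(find_local_maxima(c(5, 1, 2, 1)), 2L)
  expect_error(find_local_maxima(c(1, 2)), "at least 3")
  expect_error(find_local_maxima(c(1, NA, 2)), "non-finite")
})

test_that("prominence follows the basal-line definition", {
  expect_equal(peak_prominence(c(0, 2, 1, 3, 0), 3), 3)
  expect_equal(peak_prominence(c(0, 2, 1, 3, 0), 1), 1) # saddle bounds right side
  # offset invariance: reference is the basal line, not the zero axis
  expect_equal(peak_prominence(c(0, 2, 1, 3, 0) + 50, 1), 1)
  expect_error(peak_prominence(c(0, 2, 1, 3, 0), 2), "not a local maximum")
})

test_that("width at half prominence interpolates crossings", {
  w <- peak_width(c(0, 1, 2, 3, 2, 1, 0), 3)
  expect_equal(w$left_crossing, 1.5)
  expect_equal(w$right_crossing, 4.5)
  expect_equal(w$width, 3)
  # width is invariant to positive scaling (reference scales with the signal)
  w2 <- peak_width(2 * c(0, 1, 2, 3, 2, 1, 0), 3)
  expect_equal(w2$width, 3)
  # with the topographic prominence both sides always reach the reference;
  # a larger externally supplied prominence exercises the clamp path
  w3 <- peak_width(c(0, 4, 3, 3.5), 1, prominence = 4)
  expect_true(w3$clamped)
  expect_equal(w3$right_crossing, 3)
})

test_that("width of a sampled Gaussian lobe matches the closed-form FWHM", {
  sigma <- 20
  x <- 150 * exp(-((0:200) - 100)^2 / (2 * sigma^2))
  pk <- find_peaks(x, min_prominence = 100)
  expect_equal(pk$index, 100L)
  expect_equal(pk$width, 2 * sigma * sqrt(2 * log(2)), tolerance = 0.5 / pk$width)
})

test_that("find_peaks filters on prominence and keeps first-in-time", {
  pk <- find_peaks(c(0, 120, 0, 90, 0), min_prominence = 100, n_peaks = 1)
  expect_equal(pk$index, 1L) # 90 deg/s peak fails the filter
  pk <- find_peaks(c(0, 90, 0, 120, 0), min_prominence = 100, n_peaks = 1)
  expect_equal(pk$index, 3L) # first passing peak in time order
  expect_equal(nrow(find_peaks(c(0, 50, 0), min_prominence = 100)), 0L)
  # max_prominence selection picks the taller peak instead
  pk <- find_peaks(c(0, 110, 0, 120, 0),
    min_prominence = 100, n_peaks = 1,
    selection = "max_prominence"
  )
  expect_equal(pk$index, 3L)
  pk <- find_peaks(c(0, 110, 0, 120, 0), min_prominence = 100, n_peaks = 1)
  expect_equal(pk$index, 1L)
})

test_that("prominence is offset-invariant and width scale-invariant (property)", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      x <- random_trace()
      pk <- find_peaks(x, min_prominence = 1, n_peaks = 100)
      if (nrow(pk) == 0) next
      shifted <- find_peaks(x + 37.5, min_prominence = 1, n_peaks = 100)
      expect_equal(shifted$prominence, pk$prominence)
      expect_equal(shifted$index, pk$index)
      scaled <- find_peaks(3 * (x - min(x)) + 1, min_prominence = 1, n_peaks = 100)
      expect_equal(scaled$width, pk$width, tolerance = 1e-12)
    }
  })
})

test_that("returned peaks have ordered crossings at the reference height", {
  withr::with_seed(12, {
    for (rep in 1:50) {
      x <- random_trace()
      pk <- find_peaks(x, min_prominence = 5, n_peaks = 100)
      for (i in seq_len(nrow(pk))) {
        expect_lt(pk$left_crossing[i], pk$index[i])
        expect_gt(pk$right_crossing[i], pk$index[i])
        ref <- pk$velocity[i] - pk$prominence[i] / 2
        expect_gte(pk$velocity[i], ref)
        for (cr in c(pk$left_crossing[i], pk$right_crossing[i])) {
          v <- approx(seq_along(x) - 1, x, xout = cr)$y
          expect_lte(v, ref + 1e-9)
        }
      }
    }
  })
})

test_that("raising min_prominence never increases the peak count", {
  withr::with_seed(13, {
    for (rep in 1:30) {
      x <- random_trace()
      counts <- vapply(
        c(1, 25, 50, 100, 150, 200),
        function(mp) nrow(find_peaks(x, mp, n_peaks = 100)),
        numeric(1)
      )
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("find_peaks agrees with the brute-force oracle on random traces", {
  withr::with_seed(14, {
    for (rep in 1:150) {
      x <- random_trace()
      mp <- sample(c(1, 20, 80, 100), 1)
      np <- sample(1:3, 1)
      got <- find_peaks(x, mp, np)
      want <- oracle_find_peaks(x, mp, np)
      expect_identical(as.integer(got$index), as.integer(want$index))
      expect_identical(got$prominence, want$prominence)
      expect_equal(got$width, want$width, tolerance = 1e-9)
    }
  })
})
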