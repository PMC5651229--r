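#' Topographic peak detection on a velocity trace
#'
#' Peak detection for 1-D angular-velocity traces as used throughout SHIMP
#' (suppression head impulse paradigm) analysis: strict local maxima,
#' topographic prominence relative to the basal velocity line (not the
#' zero-velocity axis), and full width at half prominence with linearly
#' interpolated crossings. This mirrors the behaviour of a findpeaks-style
#' routine configured with a single output peak and a minimum-prominence
#' filter.
#'
#' Sample positions are 0-based throughout (`index = 0` is the first sample),
#' matching the on-disk trace dialect, so detected indices line up with the
#' `sample_index` column of trace files.
#'
#' @param x Numeric vector of angular velocities (deg/s). Must have at least
#'   3 finite samples.
#' @param min_prominence Minimum topographic prominence (deg/s) for a peak to
#'   be kept; peaks with prominence greater than or equal to this value pass.
#' @param n_peaks Maximum number of peaks returned.
#' @param selection How to pick when more than `n_peaks` candidates pass the
#'   prominence filter: `"first"` keeps the earliest in time (the behaviour of
#'   the routine this re-implements), `"max_prominence"` keeps the most
#'   prominent.
#'
#' @return A tibble with one row per detected peak and columns
#'   \describe{
#'     \item{index}{0-based sample position of the apex (integer).}
#'     \item{velocity}{apex value (deg/s).}
#'     \item{prominence}{apex value minus the basal reference (deg/s).}
#'     \item{width}{full width in samples at half prominence (fractional).}
#'     \item{left_crossing,right_crossing}{fractional 0-based sample positions
#'       of the half-prominence crossings.}
#'     \item{width_clamped}{TRUE when a crossing ran off the trace end and was
#'       clamped there.}
#'   }
#'   Zero rows when no candidate passes the filter.
#'
#' @examples
#' find_peaks(c(0, 120, 0, 90, 0), min_prominence = 100)
#' find_peaks(c(0, 90, 0, 120, 0), min_prominence = 100)
#' @export
find_peaks <- function(x, min_prominence, n_peaks = 1L,
                       selection = c("first", "max_prominence")) {
  selection <- match.arg(selection)
  validate_trace(x)
  stopifnot(min_prominence > 0, n_peaks >= 1)

  cand <- find_local_maxima(x)
  if (length(cand) == 0L) {
    return(empty_peaks())
  }
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) {
    return(empty_peaks())
  }
  if (selection == "max_prominence") {
    ord <- order(-prom, cand)
  } else {
    ord <- order(cand)
  }
  sel <- ord[seq_len(min(n_peaks, length(cand)))]
  sel <- sel[order(cand[sel])] # always report in time order
  rows <- purrr::map2(cand[sel], prom[sel], function(i, p) {
    w <- peak_width(x, i, p)
    tibble::tibble(
      index = i,
      velocity = x[i + 1L],
      prominence = p,
      width = w$width,
      left_crossing = w$left_crossing,
      right_crossing = w$right_crossing,
      width_clamped = w$clamped
    )
  })
  dplyr::bind_rows(rows)
}

empty_peaks <- function() {
  tibble::tibble(
    index = integer(), velocity = double(), prominence = double(),
    width = double(), left_crossing = double(), right_crossing = double(),
    width_clamped = logical()
  )
}

validate_trace <- function(x) {
  if (!is.numeric(x) || length(x) < 3L) {
    stop("velocity trace must be numeric with at least 3 samples", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("velocity trace contains non-finite samples", call. = FALSE)
  }
  invisible(x)
}

#' Strict local maxima of a trace
#'
#' Interior samples strictly above both neighbours. A flat-topped run of equal
#' values strictly above both flanking values counts once, at the first sample
#' of the run. Endpoints are never candidates.
#'
#' @inheritParams find_peaks
#' @return Integer vector of 0-based candidate apex positions (possibly empty).
#' @examples
#' find_local_maxima(c(0, 2, 2, 2, 0)) # plateau -> first sample, position 1
#' @export
find_local_maxima <- function(x) {
  validate_trace(x)
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) {
    return(integer())
  }
  starts <- cumsum(c(1L, r$lengths[-k])) # 1-based start of each run
  j <- 2:(k - 1L)
  hit <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  as.integer(starts[j][hit] - 1L)
}

#' Topographic prominence of a local maximum
#'
#' The apex value minus the basal velocity line: extend left and right from
#' the apex until a sample strictly higher than the apex (or the trace end) is
#' reached, take the minimum on each side, and subtract the higher of the two
#' minima. Adding a constant to the whole trace leaves prominence unchanged —
#' the reference is the local baseline, never the zero-velocity axis.
#'
#' @inheritParams find_peaks
#' @param index 0-based position of a local maximum of `x`.
#' @return Prominence in deg/s (positive scalar).
#' @examples
#' peak_prominence(c(0, 2, 1, 3, 0), 1) # saddle at 1 bounds the right side
#' @export
peak_prominence <- function(x, index) {
  validate_trace(x)
  i <- as.integer(index) + 1L # to 1-based
  n <- length(x)
  if (i < 2L || i > n - 1L || !(index %in% find_local_maxima(x))) {
    stop("index ", index, " is not a local maximum of the trace", call. = FALSE)
  }
  apex <- x[i]
  left_min <- apex
  j <- i - 1L
  while (j >= 1L && x[j] <= apex) {
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  right_min <- apex
  j <- i + 1L
  while (j <= n && x[j] <= apex) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  apex - max(left_min, right_min)
}

#' Width at half prominence
#'
#' The reference height is the apex value minus half the prominence. From the
#' apex, walk outward to the first sample at or below the reference on each
#' side; the crossing position is linearly interpolated between the bracketing
#' samples. A side that never drops to the reference before the trace end
#' clamps to that end and sets `clamped`.
#'
#' @inheritParams peak_prominence
#' @param prominence Topographic prominence of the peak at `index`; computed
#'   with [peak_prominence()] when not supplied.
#' @return List with `width` (samples), `left_crossing`, `right_crossing`
#'   (fractional 0-based positions) and `clamped` (logical).
#' @examples
#' peak_width(c(0, 1, 2, 3, 2, 1, 0), 3) # width 3.0, crossings 1.5 / 4.5
#' @export
peak_width <- function(x, index, prominence = NULL) {
  validate_trace(x)
  if (is.null(prominence)) prominence <- peak_prominence(x, index)
  stopifnot(prominence > 0)
  i <- as.integer(index) + 1L
  n <- length(x)
  ref <- x[i] - prominence / 2

  clamped <- FALSE
  # left crossing
  j <- i - 1L
  while (j >= 1L && x[j] > ref) j <- j - 1L
  if (j < 1L) {
    left <- 0
    clamped <- TRUE
  } else {
    # x[j] <= ref < x[j + 1]; interpolate on [j, j + 1]
    left <- if (x[j] == ref) j - 1L else (j - 1L) + (ref - x[j]) / (x[j + 1L] - x[j])
  }
  # right crossing
  j <- i + 1L
  while (j <= n && x[j] > ref) j <- j + 1L
  if (j > n) {
    right <- n - 1L
    clamped <- TRUE
  } else {
    right <- if (x[j] == ref) j - 1L else (j - 2L) + (ref - x[j - 1L]) / (x[j] - x[j - 1L])
  }
  list(
    width = as.numeric(right - left),
    left_crossing = as.numeric(left),
    right_crossing = as.numeric(right),
    clamped = clamped
  )
}
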