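#' Per-test SHIMP summary
#'
#' Aggregates per-impulse analyses into the per-test statistics the analysis
#' method reports: impulse count, mean head peak velocity, number of head
#' impulses with apex velocity under 130 deg/s (strict), first-saccade
#' latency mean and SD, number and percentage of early saccades, the list of
#' early impulse ids, and latency/width/velocity mean and SD separately for
#' early and not-early saccades.
#'
#' The "first saccade" of an impulse is its single detected saccade, early or
#' not. All means and SDs are over impulses where the quantity exists; SD is
#' the sample SD (n - 1 denominator). `pct_early` is a percentage of detected
#' saccades (impulses without a saccade affect `n_impulses` only) and is `NA`
#' when no saccade was detected.
#'
#' @param analyses A `shimp_analysis` tibble from [analyze_impulses()], or any
#'   tibble with its columns.
#' @param config An [shimp_config()] object (supplies the low-velocity
#'   threshold); defaults to the configuration stored in `analyses`.
#' @return A one-row tibble of class `shimp_summary`; `early_impulse_ids` is
#'   a list-column.
#' @examples
#' sim <- simulate_test(10, preset = "predictable", seed = 1)
#' analyze_impulses(sim$traces) |> summarize_test()
#' @export
summarize_test <- function(analyses, config = NULL) {
  if (nrow(analyses) == 0L) {
    stop("cannot summarize an empty analysis table", call. = FALSE)
  }
  config <- as_shimp_config(config %||% attr(analyses, "config") %||% shimp_config())
  rate <- attr(analyses, "rate_hz") %||% NA_real_

  has_sacc <- !is.na(analyses$saccade_index)
  early <- analyses$early & has_sacc
  stats_of <- function(rows, prefix) {
    out <- tibble::tibble(
      n = sum(rows, na.rm = TRUE),
      latency_mean_ms = mean_or_na(analyses$latency_ms[which(rows)]),
      latency_sd_ms = sd_or_na(analyses$latency_ms[which(rows)]),
      width_mean_ms = mean_or_na(analyses$saccade_width_ms[which(rows)]),
      width_sd_ms = sd_or_na(analyses$saccade_width_ms[which(rows)]),
      velocity_mean_degps = mean_or_na(analyses$saccade_velocity[which(rows)]),
      velocity_sd_degps = sd_or_na(analyses$saccade_velocity[which(rows)])
    )
    names(out) <- paste0(prefix, "_", names(out))
    out
  }

  out <- dplyr::bind_cols(
    tibble::tibble(
      n_impulses = nrow(analyses),
      n_saccades = sum(has_sacc),
      mean_head_peak_velocity = mean_or_na(analyses$head_velocity),
      n_head_below_130 = sum(analyses$head_velocity < config$low_velocity_threshold,
        na.rm = TRUE
      ),
      first_saccade_latency_mean_ms = mean_or_na(analyses$latency_ms[has_sacc]),
      first_saccade_latency_sd_ms = sd_or_na(analyses$latency_ms[has_sacc]),
      n_early = sum(early, na.rm = TRUE),
      pct_early = if (any(has_sacc)) {
        100 * sum(early, na.rm = TRUE) / sum(has_sacc)
      } else {
        NA_real_
      }
    ),
    stats_of(early, "early"),
    stats_of(!early & has_sacc, "not_early"),
    tibble::tibble(
      early_impulse_ids = list(analyses$impulse_id[which(early)])
    )
  )
  structure(out,
    class = c("shimp_summary", class(out)),
    rate_hz = rate
  )
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) NA_real_ else stats::sd(x)
}

#' Compare mean first-saccade latencies between protocols
#'
#' Descriptive comparison of SHIMP protocols (for example predictable vs
#' unpredictable head-impulse delivery): the per-protocol mean first-saccade
#' latency is the unweighted mean of the per-test latency means, and every
#' ordered pair of protocols gets a mean difference. Differences are
#' antisymmetric by construction: `difference(a, b) = -difference(b, a)`. No
#' inferential statistics are computed.
#'
#' @param summaries A tibble with one row per test, a protocol label column
#'   and a per-test mean latency column — typically per-test
#'   [summarize_test()] rows bound together with a `protocol` column added.
#' @param protocol,latency Column names (strings) of the protocol label and
#'   the per-test mean latency (ms).
#' @return An object of class `shimp_protocol_comparison`: a list with
#'   `means` (protocol, n_tests, mean_latency_ms) and `differences`
#'   (protocol_a, protocol_b, difference_ms = mean_a - mean_b). [tidy()]
#'   returns the differences tibble.
#' @examples
#' tab <- tibble::tibble(
#'   protocol = c("predictable", "less_predictable", "unpredictable"),
#'   first_saccade_latency_mean_ms = c(112.8, 152.04, 178.32)
#' )
#' compare_protocol_means(tab)
#' @export
compare_protocol_means <- function(summaries, protocol = "protocol",
                                   latency = "first_saccade_latency_mean_ms") {
  stopifnot(protocol %in% names(summaries), latency %in% names(summaries))
  means <- summaries |>
    dplyr::group_by(protocol = .data[[protocol]]) |>
    dplyr::summarise(
      n_tests = dplyr::n(),
      mean_latency_ms = mean_or_na(.data[[latency]]),
      .groups = "drop"
    )
  bad <- is.na(means$mean_latency_ms)
  if (any(bad)) {
    warning(
      "protocol(s) without latency data excluded: ",
      paste(means$protocol[bad], collapse = ", ")
    )
    means <- means[!bad, ]
  }
  if (nrow(means) < 2L) {
    stop("need at least two protocols with latency data", call. = FALSE)
  }
  pairs <- tidyr::expand_grid(
    protocol_a = means$protocol,
    protocol_b = means$protocol
  ) |>
    dplyr::filter(.data$protocol_a != .data$protocol_b) |>
    dplyr::mutate(
      difference_ms = means$mean_latency_ms[match(.data$protocol_a, means$protocol)] -
        means$mean_latency_ms[match(.data$protocol_b, means$protocol)]
    )
  structure(list(means = means, differences = pairs),
    class = "shimp_protocol_comparison"
  )
}

#' @export
print.shimp_protocol_comparison <- function(x, ...) {
  cat("Protocol mean first-saccade latencies (ms):\n")
  print(x$means, ...)
  cat("\nPairwise mean differences (ms):\n")
  print(x$differences, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname summarize_test
#' @param x,... For the `tidy`/`glance` methods: the object and ignored
#'   further arguments.
#' @method glance shimp_analysis
#' @export
glance.shimp_analysis <- function(x, ...) {
  summarize_test(x)
}

#' @rdname summarize_test
#' @method tidy shimp_analysis
#' @export
tidy.shimp_analysis <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "shimp_analysis")
  out
}

#' @rdname compare_protocol_means
#' @param x,... For the `tidy` method: the comparison object and ignored
#'   further arguments.
#' @method tidy shimp_protocol_comparison
#' @export
tidy.shimp_protocol_comparison <- function(x, ...) {
  x$differences
}

#' @rdname compare_protocol_means
#' @method glance shimp_protocol_comparison
#' @export
glance.shimp_protocol_comparison <- function(x, ...) {
  x$means
}
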