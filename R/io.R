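trace_columns <- c(
  "impulse_id", "side", "sample_index",
  "head_velocity_degps", "eye_velocity_degps"
)

#' Read a SHIMP test from the open CSV dialect
#'
#' The vendor database export format is proprietary, so this package defines
#' an open, documented dialect instead. The CSV layout is long format with a
#' header row `impulse_id,side,sample_index,head_velocity_degps,`
#' `eye_velocity_degps`, optionally preceded by `# key=value` comment lines
#' carrying `test_id`, `protocol`, `rate_hz` and `device`. `sample_index`
#' must be contiguous from 0 within each impulse.
#'
#' @param path Path to the CSV file.
#' @param rate_hz Optional override of the sampling rate; otherwise taken
#'   from the `# rate_hz=` header, else 250 with a warning.
#' @return A long trace tibble (columns above) with attributes `rate_hz`,
#'   `test_id`, `protocol`, `device`; feed it to [analyze_impulses()].
#' @export
read_shimp_csv <- function(path, rate_hz = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, n = 50L)
  meta <- parse_header_meta(grep("^#", lines, value = TRUE))
  # col_types of an absent column would warn; the schema check below reports it
  traces <- suppressWarnings(readr::read_csv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      impulse_id = readr::col_character(),
      side = readr::col_character(),
      sample_index = readr::col_integer(),
      head_velocity_degps = readr::col_double(),
      eye_velocity_degps = readr::col_double()
    )
  ))
  missing <- setdiff(trace_columns, names(traces))
  if (length(missing) > 0L) {
    stop("schema error in ", path, ": missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  traces <- traces[trace_columns]
  finish_traces(traces, meta, rate_hz, path)
}

#' Read a SHIMP test from the open XML dialect
#'
#' The documented dialect is
#' `<shimp_test rate_hz="250" ...><impulse id="imp001" side="right">`
#' `<head>space-separated deg/s values</head><eye>...</eye></impulse>...`
#' `</shimp_test>`; `test_id`, `protocol` and `device` are optional root
#' attributes. Head and eye of an impulse must have equal length. This is an
#' original dialect, not the vendor's schema.
#'
#' @inheritParams read_shimp_csv
#' @return Same as [read_shimp_csv()]; CSV and XML encodings of the same
#'   content yield equal tibbles.
#' @export
read_shimp_xml <- function(path, rate_hz = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  doc <- xml2::read_xml(path) # malformed XML -> parse error with line number
  root <- xml2::xml_name(doc)
  if (root != "shimp_test") {
    stop("schema error in ", path, ": root element is <", root,
      ">, expected <shimp_test>",
      call. = FALSE
    )
  }
  meta <- list(
    test_id = xml2::xml_attr(doc, "test_id"),
    protocol = xml2::xml_attr(doc, "protocol"),
    rate_hz = xml2::xml_attr(doc, "rate_hz"),
    device = xml2::xml_attr(doc, "device")
  )
  meta <- meta[!vapply(meta, is.na, logical(1))]
  impulses <- xml2::xml_find_all(doc, "impulse")
  if (length(impulses) == 0L) {
    stop("schema error in ", path, ": no <impulse> elements", call. = FALSE)
  }
  rows <- purrr::map(impulses, function(node) {
    id <- xml2::xml_attr(node, "id")
    side <- xml2::xml_attr(node, "side")
    head <- parse_velocity_text(xml2::xml_find_first(node, "head"), id, path)
    eye <- parse_velocity_text(xml2::xml_find_first(node, "eye"), id, path)
    if (length(head) != length(eye)) {
      stop("integrity error in ", path, ": impulse ", id, " has ",
        length(head), " head samples but ", length(eye), " eye samples",
        call. = FALSE
      )
    }
    tibble::tibble(
      impulse_id = id,
      side = if (is.na(side)) "unknown" else side,
      sample_index = seq_along(head) - 1L,
      head_velocity_degps = head,
      eye_velocity_degps = eye
    )
  })
  finish_traces(dplyr::bind_rows(rows), meta, rate_hz, path)
}

parse_velocity_text <- function(node, id, path) {
  if (inherits(node, "xml_missing")) {
    stop("schema error in ", path, ": impulse ", id,
      " is missing a <head> or <eye> element",
      call. = FALSE
    )
  }
  vals <- suppressWarnings(
    as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  )
  if (length(vals) == 0L || anyNA(vals)) {
    stop("integrity error in ", path, ": impulse ", id,
      " has non-numeric velocity samples",
      call. = FALSE
    )
  }
  vals
}

parse_header_meta <- function(comment_lines) {
  kv <- regmatches(
    comment_lines,
    regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", comment_lines)
  )
  kv <- kv[vapply(kv, length, integer(1)) == 3L]
  stats::setNames(
    lapply(kv, function(m) m[3]),
    vapply(kv, function(m) m[2], character(1))
  )
}

finish_traces <- function(traces, meta, rate_hz, path) {
  if (is.null(rate_hz)) {
    if (!is.null(meta$rate_hz)) {
      rate_hz <- as.numeric(meta$rate_hz)
    } else {
      warning("no rate_hz in ", path, "; assuming 250 Hz")
      rate_hz <- 250
    }
  }
  if (anyDuplicated(unique(traces[c("impulse_id", "side")])$impulse_id) > 0L) {
    stop("integrity error in ", path, ": duplicated impulse_id", call. = FALSE)
  }
  check <- traces |>
    dplyr::group_by(.data$impulse_id) |>
    dplyr::summarise(
      ok = all(.data$sample_index == seq_len(dplyr::n()) - 1L),
      .groups = "drop"
    )
  if (any(!check$ok)) {
    stop("integrity error in ", path, ": sample_index not contiguous from 0 ",
      "for impulse(s) ", paste(check$impulse_id[!check$ok], collapse = ", "),
      call. = FALSE
    )
  }
  attr(traces, "rate_hz") <- rate_hz
  attr(traces, "test_id") <- meta$test_id %||% NA_character_
  attr(traces, "protocol") <- meta$protocol %||% NA_character_
  attr(traces, "device") <- meta$device %||% NA_character_
  traces
}

#' Write a SHIMP test to the open CSV dialect
#'
#' @param traces Long trace tibble (see [read_shimp_csv()] for columns).
#' @param path Output path.
#' @param rate_hz Sampling rate written to the header; defaults to the
#'   tibble's `rate_hz` attribute, else 250.
#' @param test_id,protocol,device Optional metadata written as `# key=value`
#'   header lines; default to the tibble's attributes.
#' @return `path`, invisibly. Velocities are serialized with 6 decimals.
#' @export
write_shimp_csv <- function(traces, path, rate_hz = NULL, test_id = NULL,
                            protocol = NULL, device = NULL) {
  check_traces(traces)
  meta <- output_meta(traces, rate_hz, test_id, protocol, device)
  header <- sprintf("# %s=%s", names(meta), unlist(meta))
  body <- sprintf(
    "%s,%s,%d,%.6f,%.6f",
    traces$impulse_id, traces$side, traces$sample_index,
    traces$head_velocity_degps, traces$eye_velocity_degps
  )
  writeLines(
    c(header, paste(trace_columns, collapse = ","), body),
    path
  )
  invisible(path)
}

#' Write a SHIMP test to the open XML dialect
#'
#' @inheritParams write_shimp_csv
#' @return `path`, invisibly.
#' @export
write_shimp_xml <- function(traces, path, rate_hz = NULL, test_id = NULL,
                            protocol = NULL, device = NULL) {
  check_traces(traces)
  meta <- output_meta(traces, rate_hz, test_id, protocol, device)
  doc <- xml2::xml_new_root("shimp_test")
  for (nm in names(meta)) xml2::xml_set_attr(doc, nm, meta[[nm]])
  for (id in unique(traces$impulse_id)) {
    g <- traces[traces$impulse_id == id, ]
    g <- g[order(g$sample_index), ]
    node <- xml2::xml_add_child(doc, "impulse", id = id, side = g$side[1])
    xml2::xml_add_child(
      node, "head",
      paste(sprintf("%.6f", g$head_velocity_degps), collapse = " ")
    )
    xml2::xml_add_child(
      node, "eye",
      paste(sprintf("%.6f", g$eye_velocity_degps), collapse = " ")
    )
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

output_meta <- function(traces, rate_hz, test_id, protocol, device) {
  meta <- list(
    test_id = test_id %||% attr(traces, "test_id"),
    protocol = protocol %||% attr(traces, "protocol"),
    rate_hz = rate_hz %||% attr(traces, "rate_hz") %||% 250,
    device = device %||% attr(traces, "device")
  )
  drop <- vapply(meta, function(v) is.null(v) || is.na(v), logical(1))
  lapply(meta[!drop], format)
}

results_schema_version <- "1.0"

#' Write analysis results to JSON
#'
#' Serializes a test summary and its per-impulse analyses to a stable-key,
#' versioned JSON document: `schema_version`, `metadata`, `summary`, and one
#' `impulses` entry per impulse (peaks, saccade measure, ESTP, early flag and
#' the QC flags that are set). Milliseconds and deg/s are rounded to 2
#' decimals; missing values are `null`. Key order is canonical, so the same
#' results always serialize byte-identically ([read_results_json()] plus
#' re-serialization round-trips exactly).
#'
#' @param summary A [summarize_test()] row.
#' @param analyses The matching [analyze_impulses()] tibble.
#' @param path Output path.
#' @param metadata Named list merged into the `metadata` object (for example
#'   `test_id`, `protocol`).
#' @return `path`, invisibly.
#' @export
write_results_json <- function(summary, analyses, path, metadata = list()) {
  payload <- results_payload(summary, analyses, metadata)
  writeLines(results_to_json(payload), path)
  invisible(path)
}

results_payload <- function(summary, analyses, metadata = list()) {
  r2 <- function(x) {
    ifelse(is.na(x), NA_real_, round(as.numeric(x), 2))
  }
  meta <- c(
    list(rate_hz = attr(analyses, "rate_hz") %||% NA_real_),
    metadata
  )
  impulses <- purrr::map(seq_len(nrow(analyses)), function(i) {
    a <- analyses[i, ]
    qc <- names(a)[startsWith(names(a), "qc_") & unlist(a[startsWith(names(a), "qc_")])]
    list(
      impulse_id = a$impulse_id,
      side = a$side,
      sign = as.numeric(a$sign),
      head_index = as.integer(a$head_index),
      head_velocity_degps = r2(a$head_velocity),
      head_prominence_degps = r2(a$head_prominence),
      head_width_ms = r2(a$head_width_ms),
      vor_index = as.integer(a$vor_index),
      vor_prominence_degps = r2(a$vor_prominence),
      saccade_index = as.integer(a$saccade_index),
      saccade_velocity_degps = r2(a$saccade_velocity),
      saccade_width_ms = r2(a$saccade_width_ms),
      latency_ms = r2(a$latency_ms),
      estp_samples = r2(a$estp_samples),
      early = a$early,
      qc = I(sub("^qc_", "", qc))
    )
  })
  list(
    schema_version = results_schema_version,
    metadata = meta,
    summary = list(
      n_impulses = as.integer(summary$n_impulses),
      n_saccades = as.integer(summary$n_saccades),
      mean_head_peak_velocity_degps = r2(summary$mean_head_peak_velocity),
      n_head_below_130 = as.integer(summary$n_head_below_130),
      first_saccade_latency_mean_ms = r2(summary$first_saccade_latency_mean_ms),
      first_saccade_latency_sd_ms = r2(summary$first_saccade_latency_sd_ms),
      n_early = as.integer(summary$n_early),
      pct_early = r2(summary$pct_early),
      early_latency_mean_ms = r2(summary$early_latency_mean_ms),
      early_latency_sd_ms = r2(summary$early_latency_sd_ms),
      early_width_mean_ms = r2(summary$early_width_mean_ms),
      early_width_sd_ms = r2(summary$early_width_sd_ms),
      early_velocity_mean_degps = r2(summary$early_velocity_mean_degps),
      early_velocity_sd_degps = r2(summary$early_velocity_sd_degps),
      not_early_latency_mean_ms = r2(summary$not_early_latency_mean_ms),
      not_early_latency_sd_ms = r2(summary$not_early_latency_sd_ms),
      not_early_width_mean_ms = r2(summary$not_early_width_mean_ms),
      not_early_width_sd_ms = r2(summary$not_early_width_sd_ms),
      not_early_velocity_mean_degps = r2(summary$not_early_velocity_mean_degps),
      not_early_velocity_sd_degps = r2(summary$not_early_velocity_sd_degps),
      early_impulse_ids = I(unlist(summary$early_impulse_ids) %||% character())
    ),
    impulses = impulses
  )
}

results_to_json <- function(payload) {
  jsonlite::toJSON(payload,
    auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE, null = "null"
  )
}

#' Read an analysis results JSON file
#'
#' Parses a file written by [write_results_json()] back into its canonical
#' payload (a nested list mirroring the JSON). Re-serializing the result
#' reproduces the file byte for byte.
#'
#' @param path Path to a results JSON file.
#' @return Nested list with `schema_version`, `metadata`, `summary`,
#'   `impulses`.
#' @export
read_results_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(payload$schema_version, results_schema_version)) {
    stop("unsupported results schema_version: ",
      format(payload$schema_version),
      call. = FALSE
    )
  }
  # restore the fields that are JSON arrays regardless of length
  payload$summary$early_impulse_ids <-
    I(as.character(unlist(payload$summary$early_impulse_ids)))
  payload$impulses <- lapply(payload$impulses, function(imp) {
    imp$qc <- I(as.character(unlist(imp$qc)))
    imp
  })
  payload
}
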