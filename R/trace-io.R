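# The electro_trace container and its CSV dialect.
#
# A trace is a tibble with columns time_s, potential_V, capacitance_F,
# area_m2 and a "metadata" attribute (named list of condition labels such as
# lipid, x_factor, dielectric_constant).  On disk: plain CSV with that exact
# header, optionally preceded or interleaved with '#'-prefixed key=value
# metadata lines.

trace_columns <- c("time_s", "potential_V", "capacitance_F", "area_m2")

#' Construct an electro_trace
#'
#' Bundles sampled channels of applied potential, measured capacitance and
#' measured bilayer area into the tibble-based container the analysis
#' pipeline consumes.
#'
#' @param time_s Sample times in s, strictly increasing.
#' @param potential_V Applied transmembrane potential in V (signed).
#' @param capacitance_F Measured membrane capacitance in F (positive).
#' @param area_m2 Measured bilayer area in m^2 (positive).
#' @param metadata Named list of free-form condition labels (e.g. `lipid`,
#'   `x_factor`, `dielectric_constant`).
#'
#' @return A tibble of class `electro_trace` with one row per sample.
#' @export
electro_trace <- function(time_s, potential_V, capacitance_F, area_m2,
                          metadata = list()) {
  out <- tibble(
    time_s = as.numeric(time_s),
    potential_V = as.numeric(potential_V),
    capacitance_F = as.numeric(capacitance_F),
    area_m2 = as.numeric(area_m2)
  )
  validate_trace(out)
  structure(out,
    metadata = metadata,
    class = c("electro_trace", class(out))
  )
}

validate_trace <- function(trace) {
  missing_cols <- setdiff(trace_columns, names(trace))
  if (length(missing_cols) > 0L) {
    stop_data(
      "trace is missing column(s): ",
      paste0("`", missing_cols, "`", collapse = ", ")
    )
  }
  if (nrow(trace) == 0L) {
    stop_data("trace has no samples.")
  }
  if (any(!is.finite(trace$time_s)) || any(diff(trace$time_s) <= 0)) {
    stop_data("`time_s` must be finite and strictly increasing.")
  }
  if (any(!is.finite(trace$capacitance_F)) || any(trace$capacitance_F <= 0)) {
    stop_data("all `capacitance_F` samples must be positive and finite.")
  }
  if (any(!is.finite(trace$area_m2)) || any(trace$area_m2 <= 0)) {
    stop_data("all `area_m2` samples must be positive and finite.")
  }
  invisible(trace)
}

#' Trace metadata
#'
#' @param trace An [electro_trace()].
#' @return The named list of condition labels attached to the trace (empty
#'   list if none).
#' @export
trace_metadata <- function(trace) {
  attr(trace, "metadata") %||% list()
}

#' Read a trace from its CSV dialect
#'
#' Expects a comma-separated file with header
#' `time_s,potential_V,capacitance_F,area_m2`; lines starting with `#` are
#' metadata of the form `# key=value` and are collected into the trace's
#' metadata list (values that parse as numbers are stored numeric).
#'
#' @param path Path to the CSV file.
#' @return An [electro_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    stop_data("trace file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  metadata <- parse_metadata(lines[is_meta])
  data_idx <- which(!is_meta & !is_blank)
  if (length(data_idx) < 2L) {
    stop_data("trace file has no data rows: ", path)
  }
  header <- strsplit(trimws(lines[data_idx[1L]]), ",")[[1L]]
  missing_cols <- setdiff(trace_columns, header)
  if (length(missing_cols) > 0L) {
    stop_data(
      "trace file missing column(s): ",
      paste0("`", missing_cols, "`", collapse = ", "),
      " (line ", data_idx[1L], ")"
    )
  }
  raw <- read.csv(
    text = paste(lines[data_idx], collapse = "\n"),
    colClasses = "character", check.names = FALSE
  )
  cols <- lapply(trace_columns, function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop_data(
        "non-numeric value in column `", col, "` at line ",
        data_idx[bad[1L] + 1L], " of ", path
      )
    }
    v
  })
  names(cols) <- trace_columns
  electro_trace(cols$time_s, cols$potential_V, cols$capacitance_F,
    cols$area_m2,
    metadata = metadata
  )
}

parse_metadata <- function(meta_lines) {
  if (length(meta_lines) == 0L) {
    return(list())
  }
  stripped <- sub("^\\s*#\\s*", "", meta_lines)
  stripped <- stripped[grepl("=", stripped, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", stripped))
  vals <- trimws(sub("^[^=]*=", "", stripped))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}

#' Write a trace to its CSV dialect
#'
#' Metadata entries are written as leading `# key=value` lines; channel values
#' are printed with 15 significant digits so that `read_trace(write_trace(x))`
#' reproduces the trace to full double precision.
#'
#' @param trace An [electro_trace()] (or data frame with the trace columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  meta <- trace_metadata(trace)
  meta_lines <- if (length(meta) > 0L) {
    vals <- vapply(meta, function(v) {
      if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
    }, character(1L))
    paste0("# ", names(meta), "=", vals)
  } else {
    character(0L)
  }
  body <- paste(
    sprintf("%.15g", trace$time_s),
    sprintf("%.15g", trace$potential_V),
    sprintf("%.15g", trace$capacitance_F),
    sprintf("%.15g", trace$area_m2),
    sep = ","
  )
  writeLines(
    c(meta_lines, paste(trace_columns, collapse = ","), body),
    path
  )
  invisible(path)
}

#' Plot the channels of a trace
#'
#' Potential (mV), capacitance (nF) and area (mm^2) against time, one facet
#' per channel.
#'
#' @param object An [electro_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.electro_trace <- function(object, ...) {
  long <- tibble(
    time_s = object$time_s,
    `potential (mV)` = object$potential_V * 1e3,
    `capacitance (nF)` = object$capacitance_F * 1e9,
    `area (mm²)` = object$area_m2 * 1e6
  ) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = unique(long$channel))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
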