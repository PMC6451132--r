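#' Write and read trace datasets
#'
#' Serializes a trace tibble to disk: one row per frame (`trace_id`,
#' `concentration`, `frame`, `donor`, `acceptor`) in CSV, or a compact
#' Parquet container for large sets, plus a JSON sidecar
#' (`<path>.meta.json`) holding the frame duration, seed and
#' concentrations.  `read_trace_dataset()` restores the tibble with its
#' `frame_dt` attribute.
#'
#' @param data A trace tibble (see [simulate_traces()]).
#' @param path Output file; the sidecar is written next to it.
#' @param format `"csv"` (default) or `"parquet"`.
#' @return `path`, invisibly (writer); the trace tibble (reader).
#' @examples
#' d <- simulate_traces(fret_model("yeast"), thermo_params(4, 10, 10),
#'                      concentration = 0, n_traces = 2, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_trace_dataset(d, f)
#' d2 <- read_trace_dataset(f)
#' attr(d2, "frame_dt")
#' @export
write_trace_dataset <- function(data, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  cols <- intersect(c("trace_id", "concentration", "frame", "donor",
                      "acceptor", "state_true", "bleached", "blinked"),
                    names(data))
  frames <- data[, cols]
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the parquet container needs the arrow package", call. = FALSE)
    }
    arrow::write_parquet(frames, path)
  } else {
    write.csv(frames, path, row.names = FALSE)
  }
  meta <- list(
    frame_dt = attr(data, "frame_dt"),
    seed = attr(data, "seed"),
    concentrations = sort(unique(data$concentration)),
    n_traces = dplyr::n_distinct(data$trace_id),
    format = format
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace_dataset
#' @export
read_trace_dataset <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  fmt <- meta$format %||% if (grepl("\\.parquet$", path)) "parquet" else "csv"
  out <- if (fmt == "parquet") {
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  }
  if (!is.null(meta$frame_dt)) attr(out, "frame_dt") <- meta$frame_dt
  if (!is.null(meta$seed)) attr(out, "seed") <- meta$seed
  out
}

#' Write and read titration-point tables
#'
#' Plain delimited I/O for fraction-classical titration points
#' (`concentration_uM`, `fc`, `sem`, `n`).
#'
#' @param points A titration-point tibble (see [fraction_classical()]).
#' @param path CSV file path.
#' @return `path`, invisibly (writer); a titration-point tibble (reader).
#' @examples
#' pts <- tibble::tibble(concentration = c(0, 10), fraction_classical = c(0.2, 0.4),
#'                       sem = c(0.01, 0.01), n_traces = c(100L, 100L))
#' f <- tempfile(fileext = ".csv")
#' write_titration_points(pts, f)
#' read_titration_points(f)
#' @export
write_titration_points <- function(points, path) {
  df <- data.frame(
    concentration_uM = points$concentration,
    fc = points$fraction_classical,
    sem = points$sem,
    n = points$n_traces
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_points
#' @export
read_titration_points <- function(path) {
  df <- read.csv(path)
  tibble::tibble(
    concentration = df$concentration_uM,
    fraction_classical = df$fc,
    sem = df$sem,
    n_traces = as.integer(df$n)
  )
}
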