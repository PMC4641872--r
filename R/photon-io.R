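#' Read a photon stream from disk
#'
#' The native interchange format is a two-column table (`macrotime_s`,
#' `microtime_ns`) with a JSON metadata sidecar next to it holding
#' `rep_rate_hz`, `duration_s`, `tick_s`, `channel_ns` and `label`. The
#' sidecar path is the data path with its extension replaced by `.json`.
#' Two on-disk encodings of the table are supported: plain CSV and Apache
#' Parquet (for large acquisitions; requires the `arrow` package).
#' Proprietary vendor formats (PTU/PT3) are out of scope; convert them to
#' this layout first.
#'
#' Macrotimes are stored in seconds in the file and snapped back onto the
#' integer tick grid (`round(macrotime_s / tick_s)`) on read, so a
#' write/read round trip is lossless.
#'
#' @param path path to the `.csv` or `.parquet` file.
#' @param format `"csv"` or `"parquet"`; default guessed from the
#'   extension.
#' @return A validated [photon_stream()].
#' @export
read_photon_stream <- function(path, format = c("auto", "csv", "parquet")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.parquet$", path, ignore.case = TRUE))
      "parquet" else "csv"
  if (!file.exists(path))
    stop("photon stream file not found: ", path, call. = FALSE)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path,
         " (expected JSON with rep_rate_hz, duration_s, tick_s)",
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("rep_rate_hz", "duration_s", "tick_s"))
    if (is.null(meta[[field]]))
      stop("metadata sidecar missing required field '", field, "'",
           call. = FALSE)
  tab <- switch(format,
    csv = utils::read.csv(path, colClasses = "numeric"),
    parquet = {
      requireNamespace_or_stop("arrow", "parquet photon streams")
      as.data.frame(arrow::read_parquet(path))
    })
  if (!all(c("macrotime_s", "microtime_ns") %in% names(tab)))
    stop("photon table must have columns macrotime_s, microtime_ns",
         call. = FALSE)
  photon_stream(
    macro_ticks   = round(tab$macrotime_s / meta$tick_s),
    microtimes_ns = tab$microtime_ns,
    rep_rate_hz   = meta$rep_rate_hz,
    duration_s    = meta$duration_s,
    tick_s        = meta$tick_s,
    channel_ns    = if (is.null(meta$channel_ns)) 0 else meta$channel_ns,
    label         = if (is.null(meta$label)) "" else meta$label
  )
}

#' Write a photon stream to disk
#'
#' Writes the two-column photon table plus the JSON metadata sidecar
#' described in [read_photon_stream()]. Macrotimes are written in seconds
#' with full double precision so the round trip is exact.
#'
#' @param stream a `photon_stream`.
#' @param path output path (`.csv` or `.parquet`).
#' @param format `"csv"` or `"parquet"`; default guessed from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_photon_stream <- function(stream, path,
                                format = c("auto", "csv", "parquet")) {
  validate_photon_stream(stream)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.parquet$", path, ignore.case = TRUE))
      "parquet" else "csv"
  tab <- data.frame(macrotime_s = macrotimes_s(stream),
                    microtime_ns = stream$microtimes_ns)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("macrotime_s,microtime_ns", con)
    if (nrow(tab))
      writeLines(paste(sprintf("%.17g", tab$macrotime_s),
                       sprintf("%.17g", tab$microtime_ns), sep = ","), con)
  } else {
    requireNamespace_or_stop("arrow", "parquet photon streams")
    arrow::write_parquet(tab, path)
  }
  meta <- list(rep_rate_hz = stream$rep_rate_hz,
               duration_s  = stream$duration_s,
               tick_s      = stream$tick_s,
               channel_ns  = stream$channel_ns,
               label       = stream$label)
  jsonlite::write_json(meta, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

requireNamespace_or_stop <- function(pkg, what) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for ", what, call. = FALSE)
}
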