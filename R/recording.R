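#' Construct a tri-axial accelerometer recording
#'
#' Container for a uniformly sampled tri-axial acceleration recording in g
#' units, as produced by a poll-mounted logger on a lunged horse. Samples
#' beyond the device measurement range are clipped to the range bound with a
#' warning, mirroring the saturation behaviour of a real +/-16 g sensor.
#'
#' @param x,y,z Numeric vectors of equal length (>= 1): acceleration in g for
#'   the three device axes. `z` is the vertical axis used by the analysis.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param device_range Saturation bound of the device in g (default 16).
#' @param meta Named list of free-form labels (horse id, group, clinical
#'   grade); kept as opaque metadata.
#'
#' @return An object of class `accel_recording`: a list with elements `x`,
#'   `y`, `z`, `sample_rate`, `device_range`, `meta`, and `n_clipped` (number
#'   of samples that hit the range bound).
#' @seealso [read_recording()], [gravity_correct()]
#' @export
accel_recording <- function(x, y, z, sample_rate, device_range = 16,
                            meta = list()) {
  assert_scalar_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  assert_scalar_number(device_range, "device_range", lower = 0, strict_lower = TRUE)
  axes <- list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  n <- unique(lengths(axes))
  if (length(n) != 1L || n < 1L)
    hs_stop("axis vectors must have equal, positive length", "hs_format_error")
  if (!all(vapply(axes, function(a) all(is.finite(a)), logical(1))))
    hs_stop("all samples must be finite", "hs_format_error")
  n_clipped <- sum(vapply(axes, function(a) sum(abs(a) > device_range),
                          integer(1)))
  if (n_clipped > 0L) {
    warning(sprintf("%d sample(s) beyond +/-%g g clipped to the device range",
                    n_clipped, device_range))
    axes <- lapply(axes, function(a) pmin(pmax(a, -device_range), device_range))
  }
  structure(list(x = axes$x, y = axes$y, z = axes$z,
                 sample_rate = as.numeric(sample_rate),
                 device_range = as.numeric(device_range),
                 meta = meta, n_clipped = as.integer(n_clipped)),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %g Hz (%.2f s), range +/-%g g\n",
              length(x$z), x$sample_rate, duration_s(x), x$device_range))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording or vertical signal in seconds
#' @param x An `accel_recording` or `vertical_signal`.
#' @return Duration in seconds.
#' @export
duration_s <- function(x) {
  n <- if (inherits(x, "accel_recording")) length(x$z) else length(x$z)
  n / x$sample_rate
}

#' Read a tri-axial recording from delimited text
#'
#' Reads a CSV or TSV export with numeric axis columns. The sampling rate may
#' be given on a comment header line of the form `# sample_rate_hz=800` or as
#' the `sample_rate` argument; one of the two is required. An optional time
#' column is ignored.
#'
#' @param path Path to a delimited text file.
#' @param sample_rate Sampling rate in Hz; overrides any header value when
#'   supplied.
#' @param column_map Named character vector mapping the axes to column names
#'   in the file, default `c(x = "ax", y = "ay", z = "az")`.
#' @param device_range Device saturation bound in g.
#' @param meta Metadata list passed through to [accel_recording()].
#' @return An [accel_recording()].
#' @export
read_recording <- function(path, sample_rate = NULL,
                           column_map = c(x = "ax", y = "ay", z = "az"),
                           device_range = 16, meta = list()) {
  if (!file.exists(path))
    hs_stop(sprintf("file not found: %s", path), "hs_config_error")
  head_lines <- readLines(path, n = 50L)
  hdr <- grep("^#\\s*sample_rate_hz\\s*=", head_lines, value = TRUE)
  if (is.null(sample_rate) && length(hdr)) {
    sample_rate <- as.numeric(sub("^#\\s*sample_rate_hz\\s*=\\s*", "", hdr[1L]))
  }
  if (is.null(sample_rate) || !is_scalar_number(sample_rate))
    hs_stop("sampling rate not found: supply `sample_rate` or a '# sample_rate_hz=' header line",
            "hs_config_error")
  first_data <- head_lines[!startsWith(head_lines, "#")][1L]
  sep <- if (grepl("\t", first_data)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(column_map), names(tab))
  if (length(missing_cols))
    hs_stop(sprintf("missing axis column(s): %s",
                    paste(missing_cols, collapse = ", ")), "hs_format_error")
  axes <- lapply(column_map, function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) & nzchar(tab[[col]]))
    if (length(bad))
      hs_stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                      tab[[col]][bad[1L]], col, bad[1L]), "hs_format_error")
    v
  })
  accel_recording(axes$x, axes$y, axes$z, sample_rate = sample_rate,
                  device_range = device_range, meta = meta)
}

#' Write a tri-axial recording as delimited text
#'
#' Writes columns `ax`, `ay`, `az` preceded by a `# sample_rate_hz=` header
#' line. Values are written with full double precision so that a
#' read/write round trip reproduces the samples exactly.
#'
#' @param rec An [accel_recording()].
#' @param path Output path.
#' @param sep Field separator, `","` (CSV, default) or `"\t"` (TSV).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "accel_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz=%.17g", rec$sample_rate), con)
  writeLines(paste(c("ax", "ay", "az"), collapse = sep), con)
  writeLines(paste(fmt_num(rec$x), fmt_num(rec$y), fmt_num(rec$z), sep = sep),
             con)
  invisible(path)
}

#' Gravity-correct the vertical axis
#'
#' Removes the static 1 g gravity component from the vertical (Z) axis so
#' that peak-detection thresholds are symmetric about zero. `method =
#' "median"` (default) subtracts the per-recording median of Z, which is
#' robust to sensor mounting tilt and equals the nominal correction for a
#' level sensor at rest; `method = "nominal"` subtracts exactly +1 g.
#'
#' @param rec An [accel_recording()].
#' @param method `"median"` or `"nominal"`.
#' @return An object of class `vertical_signal`: list with `z` (corrected
#'   vertical acceleration in g), `sample_rate`, `offset_removed` and
#'   `method`.
#' @export
gravity_correct <- function(rec, method = c("median", "nominal")) {
  stopifnot(inherits(rec, "accel_recording"))
  method <- match.arg(method)
  offset <- switch(method, median = stats::median(rec$z), nominal = 1)
  vertical_signal(rec$z - offset, rec$sample_rate, offset_removed = offset,
                  method = method)
}

#' Construct a vertical signal
#'
#' Low-level constructor for an already gravity-corrected vertical
#' acceleration trace; most users obtain one through [gravity_correct()].
#'
#' @param z Numeric vector, corrected vertical acceleration in g.
#' @param sample_rate Sampling rate in Hz.
#' @param offset_removed Offset in g that was subtracted (for audit).
#' @param method Correction method label.
#' @return A `vertical_signal` object.
#' @export
vertical_signal <- function(z, sample_rate, offset_removed = 0,
                            method = "none") {
  assert_scalar_number(sample_rate, "sample_rate", lower = 0,
                       strict_lower = TRUE)
  z <- as.numeric(z)
  if (length(z) < 1L || !all(is.finite(z)))
    hs_stop("z must be a non-empty finite numeric vector", "hs_format_error")
  structure(list(z = z, sample_rate = as.numeric(sample_rate),
                 offset_removed = as.numeric(offset_removed), method = method),
            class = "vertical_signal")
}

#' @export
print.vertical_signal <- function(x, ...) {
  cat(sprintf("<vertical_signal> %d samples @ %g Hz (%.2f s); offset removed %.4g g (%s)\n",
              length(x$z), x$sample_rate, duration_s(x), x$offset_removed,
              x$method))
  invisible(x)
}

#' Decimate a vertical signal to a lower sampling rate
#'
#' Applies an anti-aliasing FIR low-pass filter and keeps every q-th sample.
#' Only integer decimation factors are supported and upsampling is refused.
#' Decimation of impulsive signals reduces the apparent height of narrow
#' peaks, which is why the analysis operates at the native device rate; this
#' function exists to demonstrate and quantify that degradation.
#'
#' @param sig A `vertical_signal`.
#' @param target_rate Target sampling rate in Hz; must divide
#'   `sig$sample_rate`.
#' @return A `vertical_signal` at `target_rate`.
#' @export
resample_signal <- function(sig, target_rate) {
  stopifnot(inherits(sig, "vertical_signal"))
  assert_scalar_number(target_rate, "target_rate", lower = 0,
                       strict_lower = TRUE)
  if (target_rate > sig$sample_rate)
    hs_stop("upsampling is not supported (decimation only)",
            "hs_config_error")
  q <- sig$sample_rate / target_rate
  if (abs(q - round(q)) > 1e-8)
    hs_stop("target_rate must be an integer divisor of the sampling rate",
            "hs_config_error")
  q <- as.integer(round(q))
  if (q == 1L) return(sig)
  z <- signal::decimate(sig$z, q, ftype = "fir")
  vertical_signal(z, target_rate, offset_removed = sig$offset_removed,
                  method = sig$method)
}

#' Write a corrected vertical signal as single-column CSV
#'
#' @param sig A `vertical_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path) {
  stopifnot(inherits(sig, "vertical_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz=%.17g", sig$sample_rate), con)
  writeLines("z_g", con)
  writeLines(fmt_num(sig$z), con)
  invisible(path)
}

#' Read a vertical signal written by [write_signal()]
#' @param path Input path.
#' @return A `vertical_signal`.
#' @export
read_signal <- function(path) {
  head_lines <- readLines(path, n = 5L)
  hdr <- grep("^#\\s*sample_rate_hz\\s*=", head_lines, value = TRUE)
  if (!length(hdr))
    hs_stop("missing '# sample_rate_hz=' header", "hs_format_error")
  rate <- as.numeric(sub("^#\\s*sample_rate_hz\\s*=\\s*", "", hdr[1L]))
  tab <- utils::read.table(path, header = TRUE, sep = ",", comment.char = "#")
  vertical_signal(tab$z_g, rate, method = "file")
}
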