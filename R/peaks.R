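#' Peak-detection parameters
#'
#' Amplitude thresholds and minimum peak width for supra-threshold excursion
#' detection on the gravity-corrected vertical axis. The defaults are the
#' validated device settings: thresholds of -1 g and +1 g and a minimum peak
#' width of 10 samples at the native 800 Hz rate. When a signal has a
#' different sampling rate the width is rescaled so that its physical
#' duration (10/800 = 12.5 ms) is preserved.
#'
#' @param pos_threshold Positive threshold in g (> 0).
#' @param neg_threshold Negative threshold in g (< 0).
#' @param min_width_samples Minimum excursion length in samples at `ref_rate`.
#' @param ref_rate Sampling rate (Hz) at which `min_width_samples` is defined.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(pos_threshold = 1, neg_threshold = -1,
                        min_width_samples = 10, ref_rate = 800) {
  assert_scalar_number(pos_threshold, "pos_threshold", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(neg_threshold, "neg_threshold", upper = 0)
  if (neg_threshold >= 0)
    hs_stop("`neg_threshold` must be < 0", "hs_config_error")
  assert_scalar_number(min_width_samples, "min_width_samples", lower = 1)
  assert_scalar_number(ref_rate, "ref_rate", lower = 0, strict_lower = TRUE)
  structure(list(pos_threshold = pos_threshold,
                 neg_threshold = neg_threshold,
                 min_width_samples = as.integer(min_width_samples),
                 min_width_seconds = min_width_samples / ref_rate,
                 ref_rate = ref_rate),
            class = "peak_params")
}

#' @export
print.peak_params <- function(x, ...) {
  cat(sprintf("<peak_params> thresholds %+g / %+g g, min width %d samples @ %g Hz (%.4g ms)\n",
              x$pos_threshold, x$neg_threshold, x$min_width_samples,
              x$ref_rate, 1000 * x$min_width_seconds))
  invisible(x)
}

# minimum width in samples for a signal at `rate`
min_width_at <- function(params, rate) {
  if (isTRUE(all.equal(rate, params$ref_rate))) return(params$min_width_samples)
  max(1L, as.integer(round(params$min_width_seconds * rate)))
}

# maximal runs of TRUE in `cond` with length >= min_len; start/end half-open
runs_at_least <- function(cond, min_len) {
  r <- rle(cond)
  len <- r$lengths
  ends <- cumsum(len)
  starts <- ends - len + 1L
  keep <- r$values & len >= min_len
  list(start = starts[keep], len = len[keep])
}

#' Detect supra-threshold vertical-acceleration peaks
#'
#' Scans a gravity-corrected vertical signal for maximal runs of consecutive
#' samples strictly beyond the positive or negative threshold. Each run at
#' least `min_width` samples long yields one peak whose amplitude is the
#' signed extremum within the run (first occurrence on a plateau). Positive
#' and negative excursions are detected independently, so one biphasic head
#' shake contributes one positive and one negative peak. No smoothing or
#' filtering is applied.
#'
#' @param sig A `vertical_signal` (see [gravity_correct()]). The caller is
#'   responsible for gravity correction; uncorrected input shifts every
#'   excursion by 1 g.
#' @param params A [peak_params()] object.
#' @return A data frame of class `hs_peaks`, one row per peak in time order,
#'   with columns `time_s` (time of the extremum), `amplitude_g` (signed
#'   extremum), `sign` (`"positive"`/`"negative"`), `width_samples`, and the
#'   half-open sample range `start`, `end` (1-based). Attributes
#'   `sample_rate` and `duration_s` describe the source signal.
#' @export
detect_peaks <- function(sig, params = peak_params()) {
  stopifnot(inherits(sig, "vertical_signal"), inherits(params, "peak_params"))
  z <- sig$z
  w <- min_width_at(params, sig$sample_rate)
  if (length(z) < w) {
    warning("signal shorter than the minimum peak width; no peaks detectable")
    return(empty_peaks(sig))
  }
  pos <- runs_at_least(z > params$pos_threshold, w)
  neg <- runs_at_least(z < params$neg_threshold, w)
  extremum_idx <- function(starts, lens, positive) {
    vapply(seq_along(starts), function(i) {
      seg <- z[starts[i]:(starts[i] + lens[i] - 1L)]
      starts[i] + (if (positive) which.max(seg) else which.min(seg)) - 1L
    }, integer(1))
  }
  pos_idx <- extremum_idx(pos$start, pos$len, TRUE)
  neg_idx <- extremum_idx(neg$start, neg$len, FALSE)
  if (!length(pos_idx) && !length(neg_idx)) return(empty_peaks(sig))
  out <- data.frame(
    time_s = (c(pos_idx, neg_idx) - 1L) / sig$sample_rate,
    amplitude_g = z[c(pos_idx, neg_idx)],
    sign = rep(c("positive", "negative"), c(length(pos_idx), length(neg_idx))),
    width_samples = c(pos$len, neg$len),
    start = c(pos$start, neg$start),
    end = c(pos$start + pos$len, neg$start + neg$len))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  as_hs_peaks(out, sig$sample_rate, duration_s(sig))
}

empty_peaks <- function(sig = NULL) {
  out <- data.frame(time_s = numeric(0), amplitude_g = numeric(0),
                    sign = character(0), width_samples = integer(0),
                    start = integer(0), end = integer(0))
  as_hs_peaks(out, if (is.null(sig)) NA_real_ else sig$sample_rate,
              if (is.null(sig)) NA_real_ else duration_s(sig))
}

as_hs_peaks <- function(df, sample_rate, dur_s) {
  structure(df, sample_rate = sample_rate, duration_s = dur_s,
            class = c("hs_peaks", "data.frame"))
}

#' @export
print.hs_peaks <- function(x, ...) {
  cat(sprintf("<hs_peaks> %d peak(s) (%d positive, %d negative) over %.2f s\n",
              nrow(x), sum(x$sign == "positive"), sum(x$sign == "negative"),
              attr(x, "duration_s")))
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Export detected peaks as a TSV table
#'
#' Writes one row per peak (`time_s`, `amplitude_g`, `sign`,
#' `width_samples`) in time order, with full numeric precision so that
#' [read_peaks()] reproduces the peaks exactly.
#'
#' @param peaks An `hs_peaks` data frame from [detect_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "hs_peaks"))
  con <- file(path, "w")
  on.exit(close(con))
  if (is.finite(attr(peaks, "duration_s")))
    writeLines(sprintf("# duration_s=%.17g", attr(peaks, "duration_s")), con)
  writeLines(paste(c("time_s", "amplitude_g", "sign", "width_samples"),
                   collapse = "\t"), con)
  if (nrow(peaks))
    writeLines(paste(fmt_num(peaks$time_s), fmt_num(peaks$amplitude_g),
                     peaks$sign, peaks$width_samples, sep = "\t"), con)
  invisible(path)
}

#' Read a peak table written by [write_peaks()]
#' @param path Input path.
#' @return An `hs_peaks` data frame (without sample indices, which are not
#'   exported).
#' @export
read_peaks <- function(path) {
  head_lines <- readLines(path, n = 2L)
  hdr <- grep("^#\\s*duration_s\\s*=", head_lines, value = TRUE)
  dur <- if (length(hdr))
    as.numeric(sub("^#\\s*duration_s\\s*=\\s*", "", hdr[1L])) else NA_real_
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c("numeric", "numeric", "character",
                                          "integer"))
  structure(tab, duration_s = dur, sample_rate = NA_real_,
            class = c("hs_peaks", "data.frame"))
}
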