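feature_names <- function() {
  c("n_pos", "n_neg", "n_total", "ratio_pos_neg",
    "n_pos_gt2", "n_neg_lt2", "n_abs_gt2",
    "mean_pos_g", "mean_neg_g", "max_pos_g", "min_neg_g",
    "pct_pos_gt2", "pct_neg_lt2", "pct_abs_gt2",
    "pos_per_min", "neg_per_min", "total_per_min", "duration_min")
}

#' Per-recording head-movement feature vector
#'
#' Summarises one recording's detected peaks into the head-movement feature
#' set used for group comparison and diagnosis: counts of positive peaks
#' beyond +1 g and negative peaks beyond -1 g, their ratio, counts and
#' percentages beyond +/-2 g, mean and extreme amplitudes per sign, and
#' per-minute rates. Counts beyond 2 g use the same strict-inequality
#' convention as peak detection. Percentages are fractions of all detected
#' peaks (positive plus negative), so the combined percentage beyond 2 g is
#' the sum of the positive and negative percentages.
#'
#' With no negative peaks the positive:negative ratio is undefined and
#' reported as `NA` (not infinity) so that downstream nonparametric
#' statistics can drop it pairwise; with no peaks at all, counts and
#' percentages are 0 and means/extrema are `NA`.
#'
#' @param peaks An `hs_peaks` data frame from [detect_peaks()] or
#'   [read_peaks()].
#' @param duration_min Recording duration in minutes (> 0); defaults to the
#'   duration recorded on `peaks`, if any.
#' @return A one-row data frame of class `hs_features` with columns
#'   `n_pos`, `n_neg`, `n_total`, `ratio_pos_neg`, `n_pos_gt2`, `n_neg_lt2`,
#'   `n_abs_gt2`, `mean_pos_g`, `mean_neg_g`, `max_pos_g`, `min_neg_g`,
#'   `pct_pos_gt2`, `pct_neg_lt2`, `pct_abs_gt2`, `pos_per_min`,
#'   `neg_per_min`, `total_per_min`, `duration_min`.
#' @export
compute_features <- function(peaks, duration_min = NULL) {
  stopifnot(inherits(peaks, "hs_peaks"))
  if (is.null(duration_min)) {
    dur_s <- attr(peaks, "duration_s")
    if (is.null(dur_s) || !is.finite(dur_s))
      hs_stop("supply `duration_min`: the peak table carries no duration",
              "hs_config_error")
    duration_min <- dur_s / 60
  }
  assert_scalar_number(duration_min, "duration_min", lower = 0,
                       strict_lower = TRUE)
  pos <- peaks$amplitude_g[peaks$sign == "positive"]
  neg <- peaks$amplitude_g[peaks$sign == "negative"]
  n_pos <- length(pos); n_neg <- length(neg); n_total <- n_pos + n_neg
  n_pos_gt2 <- sum(pos > 2); n_neg_lt2 <- sum(neg < -2)
  pct <- function(k) if (n_total > 0) 100 * k / n_total else 0
  out <- data.frame(
    n_pos = n_pos, n_neg = n_neg, n_total = n_total,
    ratio_pos_neg = if (n_neg > 0) n_pos / n_neg else NA_real_,
    n_pos_gt2 = n_pos_gt2, n_neg_lt2 = n_neg_lt2,
    n_abs_gt2 = n_pos_gt2 + n_neg_lt2,
    mean_pos_g = if (n_pos > 0) mean(pos) else NA_real_,
    mean_neg_g = if (n_neg > 0) mean(neg) else NA_real_,
    max_pos_g = if (n_pos > 0) max(pos) else NA_real_,
    min_neg_g = if (n_neg > 0) min(neg) else NA_real_,
    pct_pos_gt2 = pct(n_pos_gt2), pct_neg_lt2 = pct(n_neg_lt2),
    pct_abs_gt2 = pct(n_pos_gt2 + n_neg_lt2),
    pos_per_min = n_pos / duration_min, neg_per_min = n_neg / duration_min,
    total_per_min = n_total / duration_min,
    duration_min = duration_min)
  structure(out, class = c("hs_features", "data.frame"))
}

#' @export
print.hs_features <- function(x, ...) {
  cat("<hs_features>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Assemble a per-horse cohort feature table
#'
#' Combines per-recording feature vectors (or peak tables, from which
#' features are computed) with group labels into the tabular form used by
#' the cohort statistics: one row per horse, columns `horse_id`, `group`,
#' then the feature fields of [compute_features()].
#'
#' @param x A list of `hs_features` rows or of `hs_peaks` tables.
#' @param labels Character vector, one group label per recording, each one of
#'   `"TGMHS"`, `"NONTGMHS"`, `"LAME"`, `"CONTROL"`.
#' @param ids Optional horse identifiers (default `"horse_01"`, ...).
#'   Duplicates are kept with a warning.
#' @param duration_min Passed to [compute_features()] when `x` holds peak
#'   tables.
#' @return A data frame of class `hs_cohort`.
#' @export
cohort_features <- function(x, labels, ids = NULL, duration_min = NULL) {
  if (!is.list(x) || !length(x))
    hs_stop("`x` must be a non-empty list of feature vectors or peak tables",
            "hs_config_error")
  if (length(labels) != length(x))
    hs_stop("need exactly one group label per recording", "hs_config_error")
  bad <- setdiff(unique(labels), hs_groups())
  if (length(bad))
    hs_stop(sprintf("unknown group label(s): %s (expected %s)",
                    paste(bad, collapse = ", "),
                    paste(hs_groups(), collapse = ", ")), "hs_config_error")
  rows <- lapply(x, function(el) {
    if (inherits(el, "hs_features")) el
    else if (inherits(el, "hs_peaks")) compute_features(el, duration_min)
    else hs_stop("list elements must be hs_features or hs_peaks",
                 "hs_config_error")
  })
  if (is.null(ids)) ids <- sprintf("horse_%02d", seq_along(x))
  if (anyDuplicated(ids))
    warning("duplicate horse id(s); rows kept as given")
  out <- cbind(data.frame(horse_id = as.character(ids),
                          group = as.character(labels),
                          stringsAsFactors = FALSE),
               do.call(rbind, lapply(rows, as.data.frame)))
  rownames(out) <- NULL
  structure(out, class = c("hs_cohort", "data.frame"))
}

#' @export
print.hs_cohort <- function(x, ...) {
  tab <- table(factor(x$group, levels = hs_groups()))
  cat(sprintf("<hs_cohort> %d horses (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
summary.hs_cohort <- function(object, features = c("ratio_pos_neg",
                                                   "mean_pos_g", "mean_neg_g", "max_pos_g", "min_neg_g",
                                                   "pct_pos_gt2", "pct_neg_lt2", "pct_abs_gt2",
                                                   "total_per_min", "pos_per_min", "neg_per_min"), ...) {
  med <- aggregate(object[features], by = list(group = object$group),
                   FUN = function(v) stats::median(v, na.rm = TRUE))
  iqr <- aggregate(object[features], by = list(group = object$group),
                   FUN = function(v) stats::IQR(v, na.rm = TRUE))
  list(median = med, iqr = iqr)
}

#' Write / read a cohort table as TSV
#' @param cohort An `hs_cohort` data frame.
#' @param path File path.
#' @return `path` (write) or an `hs_cohort` (read).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hs_cohort"))
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("horse_id", "group") %in% names(tab)))
    hs_stop("cohort table must have horse_id and group columns",
            "hs_format_error")
  structure(tab, class = c("hs_cohort", "data.frame"))
}
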