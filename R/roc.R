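#' Discrimination band for an AUC value
#'
#' Bands an AUC by the conventional diagnostic cut-points used in the
#' analysis: below 0.5 no discrimination, 0.5-0.7 poor, 0.7-0.8 acceptable,
#' 0.8-0.9 excellent and above 0.9 outstanding.
#'
#' @param auc AUC in `[0, 1]`.
#' @return One of `"none"`, `"poor"`, `"acceptable"`, `"excellent"`,
#'   `"outstanding"`.
#' @export
auc_band <- function(auc) {
  assert_scalar_number(auc, "auc", lower = 0, upper = 1)
  if (auc < 0.5) "none"
  else if (auc < 0.7) "poor"
  else if (auc < 0.8) "acceptable"
  else if (auc <= 0.9) "excellent"
  else "outstanding"
}

# empirical AUC for "higher value => case" via the midrank identity
# AUC = U_cases / (n_cases * n_controls)
rank_auc <- function(cases, controls) {
  n1 <- length(cases); n2 <- length(controls)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Empirical ROC evaluation of one feature
#'
#' Fits the empirical (trapezoidal) ROC of a single head-movement feature
#' for discriminating cases (TGMHS) from controls (all other horses), under
#' the fixed orientation "higher value indicates a case". The AUC is the
#' normalised Mann-Whitney U statistic of the cases, so features whose
#' values are lower in cases (the negative-g features) yield AUC below 0.5;
#' `effective_auc = max(auc, 1 - auc)` gives the orientation-free
#' discrimination. The confidence interval uses DeLong's method (via
#' \pkg{pROC}) by default, or a seeded stratified percentile bootstrap.
#'
#' @param cases Feature values for case horses (length >= 2).
#' @param controls Feature values for control horses (length >= 2).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates (default 2000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @param feature Optional feature label.
#' @return An object of class `hs_roc`: list with `feature`, `auc`,
#'   `effective_auc`, `ci` (length-2), `ci_method`, `band` (from
#'   [auc_band()]), `n_cases`, `n_controls`, `coords` (data frame of
#'   candidate thresholds with sensitivity and specificity under
#'   "value > threshold => case") and the input values.
#' @seealso [select_threshold()], [predictive_values()]
#' @export
hs_roc <- function(cases, controls, ci_method = c("delong", "bootstrap"),
                   boot_reps = 2000, conf_level = 0.95, seed = NULL,
                   feature = NA_character_) {
  ci_method <- match.arg(ci_method)
  cases <- as.numeric(cases[!is.na(cases)])
  controls <- as.numeric(controls[!is.na(controls)])
  if (length(cases) < 2L || length(controls) < 2L)
    hs_stop("need at least 2 non-missing values per class", "hs_stats_error")
  pooled <- c(cases, controls)
  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    warning("feature is constant across the pooled sample; AUC set to 0.5")
    auc <- 0.5
    ci <- c(0.5, 0.5)
  } else {
    auc <- rank_auc(cases, controls)
    ci <- switch(ci_method,
      delong = {
        resp <- factor(rep(c("case", "control"),
                           c(length(cases), length(controls))),
                       levels = c("control", "case"))
        r <- pROC::roc(response = resp, predictor = pooled,
                       levels = c("control", "case"), direction = "<",
                       quiet = TRUE)
        ci_obj <- pROC::ci.auc(r, method = "delong", conf.level = conf_level)
        pmin(pmax(as.numeric(ci_obj[c(1L, 3L)]), 0), 1)
      },
      bootstrap = boot_auc_ci(cases, controls, boot_reps, conf_level, seed))
  }
  structure(list(feature = feature, auc = auc,
                 effective_auc = max(auc, 1 - auc),
                 ci = ci, ci_method = if (degenerate) "degenerate" else ci_method,
                 conf_level = conf_level, band = auc_band(auc),
                 n_cases = length(cases), n_controls = length(controls),
                 coords = roc_coords(cases, controls),
                 cases = cases, controls = controls),
            class = "hs_roc")
}

boot_auc_ci <- function(cases, controls, reps, conf_level, seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  n1 <- length(cases); n2 <- length(controls)
  aucs <- vapply(seq_len(reps), function(i) {
    rank_auc(cases[sample.int(n1, n1, replace = TRUE)],
             controls[sample.int(n2, n2, replace = TRUE)])
  }, numeric(1))
  a <- (1 - conf_level) / 2
  unname(stats::quantile(aucs, c(a, 1 - a), type = 7))
}

# candidate thresholds at midpoints between adjacent distinct pooled values,
# plus sentinels; sensitivity/specificity for the rule "value > t => case"
roc_coords <- function(cases, controls) {
  v <- sort(unique(c(cases, controls)))
  thr <- c(-Inf, if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(cases > t), numeric(1))
  spec <- vapply(thr, function(t) mean(controls <= t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec,
             youden = sens + spec - 1)
}

#' @export
print.hs_roc <- function(x, ...) {
  cat(sprintf("<hs_roc>%s AUC = %.3f (%s %g%% CI %.3f-%.3f), band '%s'; %d cases vs %d controls\n",
              if (is.na(x$feature)) "" else paste0(" ", x$feature, ":"),
              x$auc, x$ci_method, 100 * x$conf_level, x$ci[1L], x$ci[2L],
              x$band, x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
plot.hs_roc <- function(x, ...) {
  ord <- order(1 - x$coords$specificity, x$coords$sensitivity)
  plot(1 - x$coords$specificity[ord], x$coords$sensitivity[ord], type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("%s (AUC %.2f)",
                      if (is.na(x$feature)) "ROC" else x$feature, x$auc),
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Select a diagnostic threshold under sensitivity/specificity constraints
#'
#' Scans the empirical ROC coordinates (thresholds at midpoints between
#' adjacent distinct observed values) for operating points with sensitivity
#' and specificity both at or above the required minima (default 0.80/0.80),
#' and among those returns the one maximising Youden's J
#' (sensitivity + specificity - 1). If no coordinate satisfies the
#' constraint the global Youden optimum is returned with
#' `constraint_met = FALSE`. The reported sensitivity and specificity are
#' exact confusion-matrix fractions of the input data at the returned
#' threshold.
#'
#' @param roc An `hs_roc` object.
#' @param min_sens,min_spec Minimum acceptable sensitivity and specificity.
#' @param direction `"auto"` (above when AUC >= 0.5, below otherwise),
#'   `"above"` (value above the threshold indicates a case) or `"below"`.
#' @return An object of class `threshold_rule`: list with `feature`,
#'   `threshold`, `direction`, `sensitivity`, `specificity`, `youden`,
#'   `constraint_met`, `provenance = "fitted"` and `suspect = FALSE`.
#' @export
select_threshold <- function(roc, min_sens = 0.80, min_spec = 0.80,
                             direction = c("auto", "above", "below")) {
  stopifnot(inherits(roc, "hs_roc"))
  direction <- match.arg(direction)
  if (direction == "auto")
    direction <- if (roc$auc >= 0.5) "above" else "below"
  if (length(unique(c(roc$cases, roc$controls))) == 1L)
    hs_stop("cannot place a threshold on a constant feature",
            "hs_stats_error")
  co <- if (direction == "above") roc$coords
        else roc_coords(-roc$cases, -roc$controls)
  co <- co[is.finite(co$threshold), , drop = FALSE]
  ok <- co$sensitivity >= min_sens & co$specificity >= min_spec
  pool <- if (any(ok)) co[ok, , drop = FALSE] else co
  pool <- pool[order(-pool$youden, -pool$sensitivity), , drop = FALSE]
  best <- pool[1L, ]
  structure(list(feature = roc$feature,
                 threshold = if (direction == "above") best$threshold
                             else -best$threshold,
                 direction = direction,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 youden = best$youden,
                 constraint_met = any(ok),
                 provenance = "fitted", suspect = FALSE),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule>%s case if value %s %.4g; sens %.2f, spec %.2f%s (%s)\n",
              if (is.na(x$feature)) "" else paste0(" ", x$feature, ":"),
              if (x$direction == "above") ">" else "<", x$threshold,
              x$sensitivity, x$specificity,
              if (isTRUE(x$constraint_met)) "" else " [constraint unmet]",
              x$provenance))
  invisible(x)
}

#' Positive and negative predictive values at a given prevalence
#'
#' Bayes' closed forms:
#' `ppv = sens * p / (sens * p + (1 - spec) * (1 - p))` and
#' `npv = spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)`.
#'
#' @param sensitivity,specificity Test characteristics in `[0, 1]`.
#' @param prevalence Case prevalence, strictly between 0 and 1.
#' @return Named numeric vector `c(ppv = , npv = )`.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  assert_scalar_number(sensitivity, "sensitivity", lower = 0, upper = 1)
  assert_scalar_number(specificity, "specificity", lower = 0, upper = 1)
  assert_scalar_number(prevalence, "prevalence", lower = 0, upper = 1)
  if (prevalence <= 0 || prevalence >= 1)
    hs_stop("predictive values are undefined at prevalence 0 or 1",
            "hs_stats_error")
  p <- prevalence
  ppv_den <- sensitivity * p + (1 - specificity) * (1 - p)
  npv_den <- specificity * (1 - p) + (1 - sensitivity) * p
  c(ppv = if (ppv_den > 0) sensitivity * p / ppv_den else NA_real_,
    npv = if (npv_den > 0) specificity * (1 - p) / npv_den else NA_real_)
}

#' ROC of one cohort feature for TGMHS versus all other horses
#'
#' Convenience wrapper: extracts a feature column from an `hs_cohort`,
#' treats TGMHS horses as cases and all others as controls, and calls
#' [hs_roc()].
#'
#' @param cohort An `hs_cohort` table.
#' @param feature Feature column name.
#' @param ... Passed to [hs_roc()].
#' @return An `hs_roc` object.
#' @export
cohort_roc <- function(cohort, feature, ...) {
  stopifnot(inherits(cohort, "hs_cohort"))
  if (!feature %in% names(cohort))
    hs_stop(sprintf("feature '%s' not in cohort table", feature),
            "hs_stats_error")
  hs_roc(cohort[[feature]][cohort$group == "TGMHS"],
         cohort[[feature]][cohort$group != "TGMHS"],
         feature = feature, ...)
}
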