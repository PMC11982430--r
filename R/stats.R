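#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, reporting the U
#' statistic for the first sample. In `"auto"` mode the exact null
#' distribution is used when the product of the sample sizes is at most 400
#' and there are no ties; otherwise the tie-corrected normal approximation
#' with continuity correction is used. The p-value computation is delegated
#' to [stats::wilcox.test()].
#'
#' @param x,y Numeric samples (each non-empty); `NA`s are dropped.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`. Requesting `"exact"`
#'   with ties falls back to the approximation with a warning.
#' @param adjusted_alpha Significance level after multiplicity adjustment;
#'   default 0.05 (no adjustment).
#' @param feature,groups Optional labels carried into the result.
#' @return A list of class `hs_group_comparison` with elements `feature`,
#'   `groups`, `test`, `statistic` (named `U`), `p_value`, `adjusted_alpha`,
#'   `significant` and `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                         adjusted_alpha = 0.05, feature = NA_character_,
                         groups = c("x", "y")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    hs_stop("both samples must be non-empty", "hs_stats_error")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  auto = n1 * n2 <= 400 && !ties,
                  exact = TRUE,
                  asymptotic = FALSE)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (exact && ties) {
    warning("exact p-value not available with ties; normal approximation used")
    exact <- FALSE
  }
  structure(list(feature = feature, groups = groups, test = "mann_whitney",
                 statistic = c(U = unname(U)), p_value = p,
                 adjusted_alpha = adjusted_alpha,
                 significant = p < adjusted_alpha,
                 method = if (exact) "exact" else "asymptotic"),
            class = "hs_group_comparison")
}

#' @export
print.hs_group_comparison <- function(x, ...) {
  cat(sprintf("<%s> %s%s: %s = %.4g, p = %.4g (%s), alpha = %.4g -> %s\n",
              x$test,
              if (is.na(x$feature)) "" else paste0(x$feature, ", "),
              paste(x$groups, collapse = " vs "),
              names(x$statistic)[1L], x$statistic[1L], x$p_value, x$method,
              x$adjusted_alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Kruskal-Wallis comparison across groups with post hoc tests
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value (delegated to
#' [stats::kruskal.test()]). When the omnibus test is significant at `alpha`,
#' pairwise Mann-Whitney post hoc tests are run at a Bonferroni-adjusted
#' alpha of `alpha` divided by the number of pairs.
#'
#' @param groups Named list of at least three numeric samples, each of size
#'   at least 2.
#' @param alpha Omnibus significance level (default 0.05).
#' @param posthoc Run pairwise post hoc tests when the omnibus test is
#'   significant?
#' @param feature Optional feature label.
#' @return A list of class `hs_kruskal`: `omnibus` (an
#'   `hs_group_comparison` with statistic `H`), `posthoc` (list of pairwise
#'   comparisons, or `NULL`) and `adjusted_alpha`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05, posthoc = TRUE,
                           feature = NA_character_) {
  if (!is.list(groups) || length(groups) < 3L)
    hs_stop("need at least 3 groups; use mann_whitney() for two",
            "hs_stats_error")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2L))
    hs_stop("each group needs at least 2 observations", "hs_stats_error")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kt <- stats::kruskal.test(groups)
  omnibus <- structure(list(feature = feature, groups = names(groups),
                            test = "kruskal_wallis",
                            statistic = c(H = unname(kt$statistic)),
                            p_value = kt$p.value, adjusted_alpha = alpha,
                            significant = kt$p.value < alpha,
                            method = "chi-square approximation"),
                       class = "hs_group_comparison")
  ph <- NULL
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  adj <- alpha / length(pairs)
  if (posthoc && omnibus$significant) {
    ph <- lapply(pairs, function(pr)
      mann_whitney(groups[[pr[1L]]], groups[[pr[2L]]],
                   adjusted_alpha = adj, feature = feature, groups = pr))
    names(ph) <- vapply(pairs, paste, character(1), collapse = " vs ")
  }
  structure(list(omnibus = omnibus, posthoc = ph, adjusted_alpha = adj),
            class = "hs_kruskal")
}

#' @export
print.hs_kruskal <- function(x, ...) {
  print(x$omnibus)
  if (is.null(x$posthoc)) {
    cat("  (no post hoc tests: omnibus not significant or disabled)\n")
  } else {
    cat(sprintf("  post hoc Mann-Whitney at adjusted alpha %.4g:\n",
                x$adjusted_alpha))
    for (cmp in x$posthoc) { cat("  "); print(cmp) }
  }
  invisible(x)
}

#' Compare feature distributions across a cohort
#'
#' Runs the cohort-level analysis over a set of features: either a series of
#' two-sided Mann-Whitney tests of TGMHS against all other horses combined
#' (`design = "tgmhs_vs_rest"`), or Kruskal-Wallis across the four groups
#' with Bonferroni-adjusted pairwise post hocs (`design = "four_group"`).
#' For the Mann-Whitney series the per-test alpha is Bonferroni-adjusted for
#' the number of features tested.
#'
#' @param cohort An `hs_cohort` table.
#' @param design `"tgmhs_vs_rest"` or `"four_group"`.
#' @param features Character vector of feature columns; default is the
#'   published comparison set.
#' @param alpha Familywise significance level.
#' @return For `"tgmhs_vs_rest"` a data frame (class `hs_cohort_tests`) with
#'   one row per feature (`U`, `p_value`, `adjusted_alpha`, `significant`);
#'   for `"four_group"` a named list of `hs_kruskal` results.
#' @export
cohort_compare <- function(cohort,
                           design = c("tgmhs_vs_rest", "four_group"),
                           features = c("ratio_pos_neg", "mean_pos_g",
                                        "mean_neg_g", "max_pos_g", "min_neg_g",
                                        "pct_pos_gt2", "pct_neg_lt2",
                                        "pct_abs_gt2", "total_per_min",
                                        "pos_per_min", "neg_per_min"),
                           alpha = 0.05) {
  stopifnot(inherits(cohort, "hs_cohort"))
  design <- match.arg(design)
  features <- intersect(features, names(cohort))
  if (!length(features))
    hs_stop("none of the requested features are in the cohort table",
            "hs_stats_error")
  if (design == "tgmhs_vs_rest") {
    adj <- alpha / length(features)
    rows <- lapply(features, function(f) {
      cmp <- tryCatch(
        mann_whitney(cohort[[f]][cohort$group == "TGMHS"],
                     cohort[[f]][cohort$group != "TGMHS"],
                     adjusted_alpha = adj, feature = f,
                     groups = c("TGMHS", "rest")),
        hs_error = function(e) NULL)
      if (is.null(cmp))
        return(data.frame(feature = f, U = NA_real_, p_value = NA_real_,
                          adjusted_alpha = adj, significant = NA,
                          method = "degenerate", stringsAsFactors = FALSE))
      data.frame(feature = f, U = unname(cmp$statistic), p_value = cmp$p_value,
                 adjusted_alpha = adj, significant = cmp$significant,
                 method = cmp$method, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(structure(out, class = c("hs_cohort_tests", "data.frame")))
  }
  res <- lapply(features, function(f) {
    g <- split(cohort[[f]], factor(cohort$group, levels = hs_groups()))
    kruskal_wallis(g, alpha = alpha, feature = f)
  })
  names(res) <- features
  res
}
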