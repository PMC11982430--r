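#' Published per-feature diagnostic threshold rules
#'
#' Returns the per-feature threshold rules from the validation study of
#' poll-mounted accelerometry in lunged horses: for each head-movement
#' feature, the ROC AUC with its confidence interval, the selected cut-off,
#' and the sensitivity and specificity published for that cut-off. The rules
#' are shipped verbatim in a constants table
#' (`system.file("extdata", "threshold_rules.tsv", package = "headshakeR")`).
#'
#' Two of the published rules — the percentage of peaks beyond +2 g and the
#' percentage beyond -2 g — carry a printed cut-off of -1.00, which is not
#' interpretable for a percentage (it would flag every recording). They are
#' kept for completeness but marked `suspect = TRUE` and excluded from
#' default rule application. The two negative-g amplitude rules have
#' `direction = "below"` (a case is indicated by a more negative value),
#' consistent with their published AUC below 0.5 under the "higher value
#' indicates a case" orientation.
#'
#' @param include_suspect Keep the two suspect percentage rules in the
#'   returned table? Default `TRUE` (they remain flagged; [apply_rules()]
#'   skips them by default regardless).
#' @return A data frame of class `hs_rules` with columns `feature`, `label`,
#'   `auc`, `ci_low`, `ci_high`, `threshold`, `sensitivity`, `specificity`,
#'   `direction`, `suspect` and `provenance = "published"`.
#' @export
default_rules <- function(include_suspect = TRUE) {
  path <- system.file("extdata", "threshold_rules.tsv",
                      package = "headshakeR", mustWork = TRUE)
  tab <- read_rules(path)
  tab$provenance <- "published"
  if (!include_suspect) tab <- tab[!tab$suspect, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read a threshold-rules table from TSV
#'
#' @param path TSV with columns `feature`, `threshold`, `sensitivity`,
#'   `specificity`, `direction`, and optionally `label`, `auc`, `ci_low`,
#'   `ci_high`, `suspect`, `provenance`.
#' @return An `hs_rules` data frame.
#' @export
read_rules <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("feature", "threshold", "sensitivity", "specificity", "direction")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    hs_stop(sprintf("rules table lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")), "hs_format_error")
  if (!all(tab$direction %in% c("above", "below")))
    hs_stop("rule direction must be 'above' or 'below'", "hs_format_error")
  if (is.null(tab$suspect)) tab$suspect <- FALSE
  if (is.null(tab$provenance)) tab$provenance <- "user"
  structure(tab, class = c("hs_rules", "data.frame"))
}

#' Apply threshold rules to a feature vector
#'
#' Evaluates each rule against a single recording's feature vector with
#' strict inequalities (value strictly beyond the cut-off in the rule's
#' direction flags the rule as met), matching the strict-threshold
#' convention of the peak detector. Rules whose feature is absent or missing
#' (`NA`) in the vector are skipped with a note; suspect rules are skipped
#' unless `include_suspect = TRUE`. The summary is the transparent fraction
#' of evaluated rules that were met — it is a set of TGMHS-consistent
#' movement flags, not a clinical diagnosis.
#'
#' @param fv An `hs_features` row (or named list / one-row data frame of
#'   feature values).
#' @param rules An `hs_rules` table, default [default_rules()].
#' @param include_suspect Evaluate the suspect rules too? Default `FALSE`.
#' @return A list of class `hs_flags`: `flags` (data frame with `feature`,
#'   `threshold`, `direction`, `value`, `met`, `skipped`), `n_met`,
#'   `n_evaluated` and `fraction_met`.
#' @export
apply_rules <- function(fv, rules = default_rules(),
                        include_suspect = FALSE) {
  if (inherits(fv, "data.frame")) {
    if (nrow(fv) != 1L)
      hs_stop("`fv` must describe exactly one recording", "hs_config_error")
    fv <- as.list(fv)
  }
  if (!is.list(fv) || is.null(names(fv)))
    hs_stop("`fv` must be a named list or one-row data frame",
            "hs_config_error")
  if (!include_suspect) rules <- rules[!rules$suspect, , drop = FALSE]
  if (!nrow(rules)) hs_stop("no rules to evaluate", "hs_config_error")
  eval_one <- function(i) {
    f <- rules$feature[i]
    val <- if (f %in% names(fv)) as.numeric(fv[[f]]) else NA_real_
    skipped <- !(f %in% names(fv)) || is.na(val)
    met <- if (skipped) NA
           else if (rules$direction[i] == "above") val > rules$threshold[i]
           else val < rules$threshold[i]
    data.frame(feature = f, threshold = rules$threshold[i],
               direction = rules$direction[i], value = val, met = met,
               skipped = skipped, stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, lapply(seq_len(nrow(rules)), eval_one))
  if (any(flags$skipped))
    message(sprintf("rule(s) skipped (feature absent or missing): %s",
                    paste(flags$feature[flags$skipped], collapse = ", ")))
  n_eval <- sum(!flags$skipped)
  if (n_eval == 0L)
    hs_stop("every rule was skipped: no evaluable features",
            "hs_stats_error")
  n_met <- sum(flags$met, na.rm = TRUE)
  structure(list(flags = flags, n_met = n_met, n_evaluated = n_eval,
                 fraction_met = n_met / n_eval),
            class = "hs_flags")
}

#' @export
print.hs_flags <- function(x, ...) {
  cat(sprintf("<hs_flags> %d of %d rules met (%.0f%%) - TGMHS-consistent movement flags\n",
              x$n_met, x$n_evaluated, 100 * x$fraction_met))
  print.data.frame(x$flags, row.names = FALSE, digits = 4)
  invisible(x)
}
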