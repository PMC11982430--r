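# Independent oracles used to cross-check the implementation.
# These are deliberately written as naive, sample-by-sample procedures,
# sharing no code with the package internals.

# Single-pass scan: walk the signal, track runs strictly beyond each
# threshold, keep runs of at least `min_width` samples, report the first
# extremum of each run.
oracle_detect_peaks <- function(z, sample_rate, pos = 1, neg = -1,
                                min_width = 10) {
  out <- data.frame(time_s = numeric(0), amplitude_g = numeric(0),
                    sign = character(0), width_samples = integer(0),
                    start = integer(0))
  flush_run <- function(out, start, i, positive) {
    len <- i - start
    if (len >= min_width) {
      seg <- z[start:(i - 1L)]
      off <- if (positive) which.max(seg) else which.min(seg)
      idx <- start + off - 1L
      out <- rbind(out, data.frame(
        time_s = (idx - 1L) / sample_rate, amplitude_g = z[idx],
        sign = if (positive) "positive" else "negative",
        width_samples = len, start = start))
    }
    out
  }
  for (positive in c(TRUE, FALSE)) {
    in_run <- FALSE
    start <- NA_integer_
    for (i in seq_along(z)) {
      beyond <- if (positive) z[i] > pos else z[i] < neg
      if (beyond && !in_run) { in_run <- TRUE; start <- i }
      if (!beyond && in_run) {
        out <- flush_run(out, start, i, positive)
        in_run <- FALSE
      }
    }
    if (in_run) out <- flush_run(out, start, length(z) + 1L, positive)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1+n2, n1) assignments of the pooled values to the first sample.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(x, y)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# AUC by direct pair counting: P(case > control) + 0.5 P(tie).
oracle_pair_auc <- function(cases, controls) {
  (sum(outer(cases, controls, ">")) +
     0.5 * sum(outer(cases, controls, "=="))) /
    (length(cases) * length(controls))
}

# Group detected >= 2 g peaks into episodes separated by > `gap_s` seconds;
# returns the onset (first peak time) of each episode.
cluster_big_peaks <- function(peaks, gap_s = 0.5, min_amp = 2) {
  big <- peaks[abs(peaks$amplitude_g) > min_amp, , drop = FALSE]
  if (!nrow(big)) return(numeric(0))
  tms <- sort(big$time_s)
  cl <- cumsum(c(1, diff(tms) > gap_s))
  as.numeric(tapply(tms, cl, min))
}

# Seeded random test signal with occasional supra-threshold excursions.
random_test_signal <- function(n, sample_rate = 800) {
  z <- stats::rnorm(n, 0, 0.6)
  # add a few smooth excursions so wide runs beyond +/-1 g exist
  k <- sample(0:4, 1)
  if (k > 0) {
    for (i in seq_len(k)) {
      len <- sample(5:min(60, n - 1), 1)
      at <- sample(seq_len(n - len), 1)
      amp <- stats::runif(1, 1, 4) * sample(c(-1, 1), 1)
      z[at:(at + len - 1L)] <- z[at:(at + len - 1L)] +
        amp * sin(pi * seq_len(len) / len)
    }
  }
  z
}
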