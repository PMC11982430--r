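test_that("generation is deterministic given a seed", {
  p <- default_profiles()$TGMHS
  s1 <- generate_recording(p, duration_min = 0.25, seed = 77)
  s2 <- generate_recording(p, duration_min = 0.25, seed = 77)
  expect_identical(s1$recording$z, s2$recording$z)
  expect_identical(s1$truth, s2$truth)

  c1 <- generate_cohort(sizes = c(TGMHS = 2, CONTROL = 2),
                        duration_min = 0.25, seed = 5)
  c2 <- generate_cohort(sizes = c(TGMHS = 2, CONTROL = 2),
                        duration_min = 0.25, seed = 5)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("a sub-threshold profile yields no peaks after correction", {
  p <- group_profile("CONTROL", pos_amp_meanlog = log(0.5),
                     pos_amp_sdlog = 0, neg_amp_meanlog = log(0.5),
                     neg_amp_sdlog = 0, noise_sd = 0, asymmetry = 0,
                     shake_rate = 0)
  sim <- generate_recording(p, duration_min = 0.5, seed = 1)
  sig <- gravity_correct(sim$recording, "median")
  expect_equal(nrow(detect_peaks(sig)), 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("generator output honours recording invariants", {
  for (g in c("TGMHS", "LAME")) {
    sim <- generate_recording(default_profiles()[[g]], duration_min = 0.5,
                              seed = 3)
    rec <- sim$recording
    expect_true(all(is.finite(rec$z)))
    expect_true(all(abs(rec$z) <= rec$device_range))
    expect_equal(length(rec$x), length(rec$z))
    expect_equal(duration_s(rec), 30)
    expect_true(all(diff(sim$truth$time_s) > 0))
    expect_true(all(sim$truth$time_s < 30))
  }
})

test_that("burst counts follow the Poisson rate within tolerance", {
  p <- group_profile("TGMHS", shake_rate = 15,
                     shake_pos_meanlog = log(5), shake_pos_sdlog = 0.25,
                     shake_neg_meanlog = log(3), shake_neg_sdlog = 0.25)
  sim <- generate_recording(p, duration_min = 5, seed = 8)
  sig <- gravity_correct(sim$recording, "median")
  pk <- detect_peaks(sig)
  n_clusters <- length(cluster_big_peaks(pk, gap_s = 0.3))
  expect_lt(abs(n_clusters - 75), 3 * sqrt(75))
})

test_that("injected bursts are recovered by detection within 50 ms", {
  # well-separated bursts (>= 3 g, <= 20/min): nearly all ground-truth events
  # must be matched by a detected >= 2 g excursion at the right time
  p <- group_profile("TGMHS", shake_rate = 12,
                     shake_pos_meanlog = log(4.5), shake_pos_sdlog = 0.15,
                     shake_neg_meanlog = log(3), shake_neg_sdlog = 0.15)
  total <- 0L; matched <- 0L
  for (s in 1:15) {
    sim <- generate_recording(p, duration_min = 1, seed = 1000 + s)
    pk <- detect_peaks(gravity_correct(sim$recording, "median"))
    big_pos <- pk$time_s[pk$amplitude_g > 2]
    for (tm in sim$truth$time_s) {
      total <- total + 1L
      if (any(abs(big_pos - tm) <= 0.05)) matched <- matched + 1L
    }
  }
  expect_gt(total, 100)
  expect_gte(matched / total, 0.95)
})

test_that("median positive-peak rate rises monotonically with shake rate", {
  # quiet baseline so the positive-peak rate is dominated by the bursts
  rates <- c(0, 6, 12, 24, 48)
  med_rate <- vapply(seq_along(rates), function(i) {
    p <- group_profile("TGMHS", pos_amp_meanlog = log(0.8),
                       pos_amp_sdlog = 0.05, neg_amp_meanlog = log(0.8),
                       neg_amp_sdlog = 0.05, shake_rate = rates[i],
                       shake_pos_meanlog = log(4), shake_pos_sdlog = 0.2)
    vals <- vapply(1:6, function(j) {
      sim <- generate_recording(p, duration_min = 1,
                                seed = 100 * i + j)
      pk <- detect_peaks(gravity_correct(sim$recording, "median"))
      compute_features(pk, duration_min = 1)$pos_per_min
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_equal(cor(rates, med_rate, method = "spearman"), 1)
})

test_that("cohort generation respects sizes and runs the real pipeline", {
  coh <- generate_cohort(sizes = c(TGMHS = 2, NONTGMHS = 2, LAME = 2,
                                   CONTROL = 2),
                         duration_min = 0.25, seed = 10)
  expect_equal(nrow(coh), 8L)
  expect_equal(sort(unique(coh$group)), sort(hs_groups()))
  expect_true(all(coh$duration_min == 0.25))
  expect_true(all(coh$total_per_min ==
                    (coh$n_pos + coh$n_neg) / coh$duration_min))
  expect_error(generate_cohort(sizes = c(BOGUS = 3)), "named")
  expect_error(generate_cohort(sizes = c(TGMHS = 0, CONTROL = 2)),
               "at least 1")
})

test_that("default cohort reproduces the published group structure", {
  coh <- generate_cohort(duration_min = 1, seed = 2024)
  expect_equal(nrow(coh), 56L)
  expect_equal(as.integer(table(coh$group)[hs_groups()]),
               c(18L, 10L, 12L, 16L))

  med <- function(g, f) median(coh[[f]][coh$group == g], na.rm = TRUE)
  # control trot baseline: total peak rate near the published 127.4/min
  expect_lt(abs(med("CONTROL", "total_per_min") - 127.4), 0.4 * 127.4)
  # headshakers show a far higher percentage of >+2 g peaks than controls
  expect_gt(med("TGMHS", "pct_pos_gt2") / max(med("CONTROL", "pct_pos_gt2"),
                                              0.5), 4)
  # lameness produces a lower positive:negative ratio than TGMHS
  expect_lt(med("LAME", "ratio_pos_neg"), med("TGMHS", "ratio_pos_neg"))
})

test_that("calibration returns the base profile at its own fixed point", {
  base <- default_profiles()["CONTROL"]
  # targets computed with the same deterministic evaluation the search uses
  feats <- c("ratio_pos_neg", "mean_pos_g", "neg_per_min")
  coh <- generate_cohort(profiles = base, sizes = c(CONTROL = 3),
                         duration_min = 0.25, seed = 55)
  tgt <- reference_medians()
  tgt <- tgt[tgt$group == "CONTROL", ]
  for (f in feats)
    tgt[[f]][tgt$stat == "median"] <- median(coh[[f]], na.rm = TRUE)
  cal <- calibrate_profiles(targets = tgt, base = base, groups = "CONTROL",
                            n_per_group = 3, duration_min = 0.25, seed = 55,
                            passes = 1, features = feats)
  expect_s3_class(cal, "hs_calibration")
  expect_equal(cal$loss[["CONTROL"]], 0, tolerance = 1e-12)
  expect_equal(cal$profiles$CONTROL$pos_amp_meanlog,
               base$CONTROL$pos_amp_meanlog)
})

test_that("calibration moves an off-target profile toward the targets", {
  base <- default_profiles()["CONTROL"]
  off <- base
  off$CONTROL$pos_amp_meanlog <- base$CONTROL$pos_amp_meanlog - 0.3
  feats <- c("pos_per_min", "neg_per_min")
  loss0 <- local({
    coh <- generate_cohort(profiles = off, sizes = c(CONTROL = 4),
                           duration_min = 0.25, seed = 9)
    tgt <- reference_medians()
    mean(abs(vapply(feats, function(f) median(coh[[f]]), numeric(1)) -
               unlist(tgt[tgt$group == "CONTROL" & tgt$stat == "median",
                          feats])) /
           unlist(tgt[tgt$group == "CONTROL" & tgt$stat == "median", feats]))
  })
  cal <- calibrate_profiles(base = off, groups = "CONTROL",
                            n_per_group = 4, duration_min = 0.25, seed = 9,
                            passes = 2, features = feats)
  expect_lte(cal$loss[["CONTROL"]], loss0 + 1e-9)
})
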