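# Synthetic band-limited EEG generator.

test_that("generation is deterministic and seed-stream separated", {
  cfg <- tiny_sim()
  r1 <- generate_recording(cfg, 1, 1, "positive")
  r2 <- generate_recording(cfg, 1, 1, "positive")
  expect_identical(r1$data, r2$data)
  # different subject or trial -> different data (subject gain + trial draws)
  expect_false(identical(generate_recording(cfg, 2, 1, "positive")$data, r1$data))
  expect_false(identical(generate_recording(cfg, 1, 2, "positive")$data, r1$data))
  expect_true(all(is.finite(r1$data)))
  expect_equal(ncol(r1$data), round(cfg$fs * cfg$duration_s))
})

test_that("labels outside the configured classes are rejected", {
  expect_error(generate_recording(tiny_sim(), 1, 1, "joy"), "not in configured")
  expect_error(sim_config(fs = 60), "too low")
  expect_error(sim_config(duration_s = 10), "first-level")
})

test_that("datasets are balanced per subject and subjects differ", {
  cfg <- tiny_sim(n_subjects = 4, trials_per_subject = 6)
  ds <- generate_dataset(cfg)
  expect_length(ds$recordings, 24L)
  counts <- table(ds$manifest$subject_id, ds$manifest$label)
  expect_true(all(counts == 3L))
  d1 <- ds$recordings[[1]]$data
  d2 <- ds$recordings[[7]]$data   # same trial slot, next subject
  expect_false(identical(d1, d2))
  # identical config regenerates the identical dataset
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$recordings[[5]]$data, ds2$recordings[[5]]$data)
})

test_that("within-region correlation exceeds cross-region correlation", {
  cfg <- tiny_sim(within_region_corr = 0.8, c = 6, n_regions = 2,
                  effect_size = 0)
  ds <- generate_dataset(cfg)
  same <- c(); cross <- c()
  regions <- cfg$region_map
  for (rec in ds$recordings[1:6]) {
    cc <- cor(t(rec$data))
    for (i in 1:5) for (j in (i + 1):6) {
      if (regions[i] == regions[j]) same <- c(same, cc[i, j])
      else cross <- c(cross, cc[i, j])
    }
  }
  expect_gt(mean(same), mean(cross))
  expect_equal(mean(same), 0.8, tolerance = 0.1)
  expect_lt(abs(mean(cross)), 0.15)
})

test_that("each band's oscillator peaks inside its own frequency range", {
  cfg <- tiny_sim(within_region_corr = 0.999, c = 2, n_regions = 1,
                  noise_exponent = 1)
  bands <- eeg_band_table()
  for (trial in 1:3) {
    rec <- generate_recording(cfg, 1, trial, "negative")
    x <- rec$data[1, ]
    n <- length(x)
    p <- Mod(fft(x - mean(x)))^2
    freq <- (seq_len(n) - 1) * cfg$fs / n
    sel <- freq > 0.5 & freq <= cfg$fs / 2
    gap <- sel & freq >= 28 & freq < 30        # no oscillator lives here
    gap_pow <- max(p[gap])
    for (j in seq_len(nrow(bands))) {
      inband <- sel & freq >= bands$f_lo[j] & freq < bands$f_hi[j]
      fpk <- freq[inband][which.max(p[inband])]
      bw <- bands$f_hi[j] - bands$f_lo[j]
      # oscillator sits well inside the band (10% edge margin by design)
      expect_gte(fpk, bands$f_lo[j] + 0.05 * bw)
      expect_lte(fpk, bands$f_hi[j] - 0.05 * bw)
      # and towers over the oscillator-free 28-30 Hz gap
      expect_gt(max(p[inband]), 20 * gap_pow)
    }
  }
})

test_that("the class contrast matches the generative power ratio and is confined to the effect band", {
  n_trials <- 200
  cfg <- tiny_sim(c = 4, n_regions = 2, effect_size = 1, trials_per_subject = 2)
  pos <- matrix(0, n_trials, 7); neg <- matrix(0, n_trials, 7)
  for (i in seq_len(n_trials)) {
    pos[i, ] <- colMeans(compute_rpsd(generate_recording(cfg, 1, i, "positive")$data, cfg$fs))
    neg[i, ] <- colMeans(compute_rpsd(generate_recording(cfg, 1, i + n_trials, "negative")$data, cfg$fs))
  }
  # boosted class mean alpha rPSD strictly exceeds the other class
  expect_gt(mean(pos[, 3]), mean(neg[, 3]))

  # oracle: analytic sinusoid band variances (amp^2/2, normalised by the
  # unboosted latent SD) plus a Monte-Carlo estimate of the unit-variance
  # background's absolute band powers, composed into expected mean rPSD
  rho <- cfg$within_region_corr
  set.seed(99)
  n_samp <- round(cfg$fs * cfg$duration_s)
  noise_abs <- rowMeans(vapply(1:50, function(i) {
    as.numeric(compute_rpsd(matrix(msgm:::pink_noise(n_samp, 1), 1), cfg$fs,
                            relative = FALSE))
  }, numeric(7)))
  expected_alpha <- function(boost) {
    amp2 <- rep(1, 7); amp2[3] <- (1 + boost)^2
    sig <- rho * (amp2 / 2) / (7 / 2)          # latent band variances
    num <- sig + (1 - rho) * noise_abs
    (num / sum(num))[3]
  }
  gap_obs <- mean(pos[, 3]) - mean(neg[, 3])
  gap_exp <- expected_alpha(cfg$effect_size) - expected_alpha(0)
  expect_equal(gap_obs, gap_exp, tolerance = 0.25 * gap_exp)

  # confinement: in ABSOLUTE band power the contrast lives only in the
  # effect band (relative features renormalise, so non-effect relative
  # bands shift by a common denominator factor instead)
  pos_abs <- matrix(0, 100, 7); neg_abs <- matrix(0, 100, 7)
  for (i in seq_len(100)) {
    pos_abs[i, ] <- colMeans(compute_rpsd(
      generate_recording(cfg, 1, i, "positive")$data, cfg$fs, relative = FALSE))
    neg_abs[i, ] <- colMeans(compute_rpsd(
      generate_recording(cfg, 1, i + n_trials, "negative")$data, cfg$fs,
      relative = FALSE))
  }
  expect_lt(t.test(pos_abs[, 3], neg_abs[, 3])$p.value, 0.01)
  # family-wise alpha = 0.01 over the six null bands (Bonferroni)
  for (j in setdiff(1:7, 3)) {
    expect_gt(t.test(pos_abs[, j], neg_abs[, j])$p.value, 0.01 / 6)
  }
  # relative band profile outside the effect band keeps its shape: the
  # between-class ratio is a common constant across non-effect bands
  ratios <- colMeans(pos[, -3]) / colMeans(neg[, -3])
  expect_lt(max(ratios) - min(ratios), 0.05)
})

test_that("a null effect leaves class band powers indistinguishable", {
  cfg <- tiny_sim(c = 4, effect_size = 0)
  n_trials <- 60
  pos <- vapply(seq_len(n_trials), function(i)
    mean(compute_rpsd(generate_recording(cfg, 1, i, "positive")$data, cfg$fs)[, 3]),
    numeric(1))
  neg <- vapply(seq_len(n_trials), function(i)
    mean(compute_rpsd(generate_recording(cfg, 1, i + n_trials, "negative")$data, cfg$fs)[, 3]),
    numeric(1))
  expect_gt(t.test(pos, neg)$p.value, 0.01)
})
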