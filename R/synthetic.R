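#' Simulation configuration for synthetic band-limited EEG
#'
#' The generator emulates the statistical structure the classifier assumes:
#' per-region latent oscillators (one sinusoid per frequency band, random
#' frequency and phase per trial), shared within a scalp region so channels
#' of a region correlate; independent 1/f^alpha background noise per
#' channel; a class-dependent amplitude boost of one band; and a per-subject
#' multiplicative gain emulating skull-thickness/impedance variability.
#'
#' @param n_subjects,trials_per_subject Cohort size. Trials are
#'   label-balanced within each subject.
#' @param c Channel count (>= 2).
#' @param fs Sampling rate (Hz); must exceed twice the 45 Hz gamma edge.
#' @param duration_s Trial length in seconds (>= the 20 s first-level window).
#' @param classes Character vector of class labels; the *last* class receives
#'   the band-power boost.
#' @param effect_band Band whose amplitude is scaled by `1 + effect_size`
#'   for the boosted class.
#' @param effect_size Relative amplitude boost (>= 0; 0 gives a null task).
#' @param region_map Named integer vector mapping channel label to region id.
#'   `NULL` partitions `c` channels into `n_regions` contiguous blocks with
#'   labels `CH01, CH02, ...`.
#' @param n_regions Number of regions for the auto-generated map.
#' @param within_region_corr Target correlation between channels sharing a
#'   region, in `[0, 1)`.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param subject_gain_sd SD of the per-subject log-normal gain.
#' @param amplitude_uv Overall channel scale in microvolts.
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 8, trials_per_subject = 8, c = 8, fs = 128,
                       duration_s = 30, classes = c("negative", "positive"),
                       effect_band = "alpha", effect_size = 1,
                       region_map = NULL, n_regions = 2,
                       within_region_corr = 0.6, noise_exponent = 1,
                       subject_gain_sd = 0.2, amplitude_uv = 20, seed = 1L) {
  bands <- eeg_band_table()
  stopifnot(c >= 2, effect_size >= 0, length(classes) >= 2,
            within_region_corr >= 0, within_region_corr < 1,
            effect_band %in% as.character(bands$band))
  if (fs <= 2 * max(bands$f_hi)) {
    stop(sprintf("fs = %g Hz too low: need > %g Hz for the %g Hz gamma edge",
                 fs, 2 * max(bands$f_hi), max(bands$f_hi)), call. = FALSE)
  }
  if (duration_s < 20) {
    stop("duration_s must be >= the 20 s first-level window", call. = FALSE)
  }
  if (is.null(region_map)) {
    labels <- sprintf("CH%02d", seq_len(c))
    region_map <- stats::setNames(sort(rep_len(seq_len(n_regions), c)), labels)
  }
  stopifnot(length(region_map) == c, !is.null(names(region_map)))
  structure(list(
    n_subjects = n_subjects, trials_per_subject = trials_per_subject,
    c = c, fs = fs, duration_s = duration_s, classes = classes,
    effect_band = effect_band, effect_size = effect_size,
    region_map = region_map, within_region_corr = within_region_corr,
    noise_exponent = noise_exponent, subject_gain_sd = subject_gain_sd,
    amplitude_uv = amplitude_uv, seed = as.integer(seed)
  ), class = "sim_config")
}

#' A raw EEG recording container
#'
#' @param data Channels-by-samples numeric matrix (microvolt scale).
#' @param fs Sampling rate (Hz).
#' @param channel_labels Unique channel labels, one per row.
#' @param subject_id,trial_id Provenance identifiers.
#' @param label Class label (or numeric valence score).
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(data, fs, channel_labels = rownames(data),
                          subject_id = NA, trial_id = NA, label = NA) {
  stopifnot(is.matrix(data), all(is.finite(data)))
  if (is.null(channel_labels)) channel_labels <- sprintf("CH%02d", seq_len(nrow(data)))
  stopifnot(length(channel_labels) == nrow(data), !anyDuplicated(channel_labels))
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id, trial_id = trial_id, label = label),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d ch x %d samples @ %g Hz | subject %s, trial %s, label %s\n",
              nrow(x$data), ncol(x$data), x$fs, x$subject_id, x$trial_id, x$label))
  invisible(x)
}

# deterministic 31-bit stream seed from configuration seed + identifiers
stream_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.numeric(p)) as.numeric(p) else sum(utf8ToInt(as.character(p)) * seq_along(utf8ToInt(as.character(p))))
  }, numeric(1))
  s <- as.numeric(seed) %% 2147483647
  for (p in parts) s <- (s * 69069 + p * custom_mix + 1) %% 2147483647
  as.integer(s)
}
custom_mix <- 2654435  # Weyl-style multiplier keeping streams for distinct ids apart

# 1/f^alpha noise via spectral synthesis, standardised to unit variance
pink_noise <- function(n, alpha = 1) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) full[nf + 1L] <- complex(real = Re(full[nf + 1L]))
  full[n:(n - nf + 2L)] <- Conj(full[2:nf])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic EEG recording
#'
#' Deterministic given `(cfg$seed, subject_id, trial_id)`: each region gets
#' one sinusoid per band with a trial-random in-band frequency and phase;
#' channels mix their region's standardised latent with independent
#' 1/f^alpha noise using weights `sqrt(rho)` and `sqrt(1 - rho)` so the
#' within-region correlation is `rho` by construction. For the boosted class
#' (last in `cfg$classes`) the `effect_band` sinusoid amplitude is scaled by
#' `1 + effect_size`.
#'
#' @param cfg A [sim_config()].
#' @param subject_id,trial_id Identifiers (integer or string).
#' @param label Class label; must be one of `cfg$classes`.
#' @return A [raw_recording()].
#' @export
generate_recording <- function(cfg, subject_id, trial_id, label) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!label %in% cfg$classes) {
    stop(sprintf("label '%s' not in configured classes (%s)",
                 label, paste(cfg$classes, collapse = ", ")), call. = FALSE)
  }
  bands <- eeg_band_table()
  n <- round(cfg$fs * cfg$duration_s)
  tgrid <- seq_len(n) / cfg$fs
  regions <- sort(unique(cfg$region_map))
  boosted <- label == cfg$classes[length(cfg$classes)]

  # subject gain: one draw per subject, independent of trial
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(stream_seed(cfg$seed, "gain", subject_id))
  gain <- exp(stats::rnorm(1, 0, cfg$subject_gain_sd))

  set.seed(stream_seed(cfg$seed, subject_id, trial_id))
  amp <- rep(1, nrow(bands))
  names(amp) <- as.character(bands$band)
  if (boosted) amp[cfg$effect_band] <- 1 + cfg$effect_size
  sigma0 <- sqrt(sum(rep(1, nrow(bands))^2) / 2)  # sd of the unboosted latent

  latents <- lapply(regions, function(r) {
    lat <- numeric(n)
    for (j in seq_len(nrow(bands))) {
      bw <- bands$f_hi[j] - bands$f_lo[j]
      fj <- stats::runif(1, bands$f_lo[j] + 0.1 * bw, bands$f_hi[j] - 0.1 * bw)
      ph <- stats::runif(1, 0, 2 * pi)
      lat <- lat + amp[j] * sin(2 * pi * fj * tgrid + ph)
    }
    lat / sigma0
  })
  names(latents) <- as.character(regions)

  rho <- cfg$within_region_corr
  data <- matrix(0, cfg$c, n, dimnames = list(names(cfg$region_map), NULL))
  for (i in seq_len(cfg$c)) {
    r <- as.character(cfg$region_map[i])
    noise <- pink_noise(n, cfg$noise_exponent)
    data[i, ] <- cfg$amplitude_uv * gain *
      (sqrt(rho) * latents[[r]] + sqrt(1 - rho) * noise)
  }
  raw_recording(data, cfg$fs, names(cfg$region_map),
                subject_id = subject_id, trial_id = trial_id, label = label)
}

#' Generate a full labelled synthetic dataset
#'
#' `n_subjects * trials_per_subject` recordings with labels cycled so every
#' class appears equally often within each subject (up to remainder when the
#' trial count is not a multiple of the class count).
#'
#' @param cfg A [sim_config()].
#' @return A list with `recordings` (list of [raw_recording()]) and
#'   `manifest` (tibble: subject_id, trial_id, label).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  recs <- list()
  rows <- list()
  idx <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (t in seq_len(cfg$trials_per_subject)) {
      lab <- cfg$classes[((t - 1L) %% length(cfg$classes)) + 1L]
      idx <- idx + 1L
      recs[[idx]] <- generate_recording(cfg, subject_id = s, trial_id = t, label = lab)
      rows[[idx]] <- tibble::tibble(subject_id = s, trial_id = t, label = lab)
    }
  }
  list(recordings = recs, manifest = dplyr::bind_rows(rows))
}

# save/restore .Random.seed so generators do not disturb the caller's RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
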