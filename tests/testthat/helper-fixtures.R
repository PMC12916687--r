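# Shared fixtures: small deterministic inputs built in code, plus naive
# reference implementations (oracles) kept independent of the package's
# vectorised paths.

# tiny simulation configuration used across tests (cheap but realistic)
tiny_sim <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 3, trials_per_subject = 4, c = 6, fs = 128,
         duration_s = 20, n_regions = 2, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# a cached small dataset + features so several tests can share the cost
tiny_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(tiny_sim())
      cache <<- prepare_features(ds, segmentation_config(scales = list(c(4, 2), c(10, 5))))
    }
    cache
  }
})

# naive per-pair Pearson correlation with the 1e-6 denominator guard
naive_pcc <- function(Z) {
  c_ <- nrow(Z)
  out <- matrix(0, c_, c_)
  for (i in seq_len(c_)) for (j in seq_len(c_)) {
    ui <- Z[i, ] - mean(Z[i, ])
    uj <- Z[j, ] - mean(Z[j, ])
    si <- sqrt(mean(ui^2)) + 1e-6
    sj <- sqrt(mean(uj^2)) + 1e-6
    out[i, j] <- mean((ui / si) * (uj / sj))
  }
  out
}

# naive dense matrix multiply (triple loop)
naive_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B)))
    for (k in seq_len(ncol(A))) out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  out
}

# naive per-step selective-scan recurrence, one (batch, channel) at a time
naive_scan <- function(v, params) {
  d <- dim(v)
  b <- d[1]; n <- d[2]; di <- d[3]
  ds <- params$d_state; dtr <- params$dt_rank
  A <- -exp(params$A_log)
  out <- array(0, d)
  for (ib in seq_len(b)) {
    x <- matrix(0, di, ds)
    for (t in seq_len(n)) {
      vt <- v[ib, t, ]
      z <- as.numeric(vt %*% params$W_x)
      delta <- log1p(exp(as.numeric(z[seq_len(dtr)] %*% params$W_dt) + params$b_dt))
      Bt <- z[dtr + seq_len(ds)]
      Ct <- z[dtr + ds + seq_len(ds)]
      for (ch in seq_len(di)) {
        x[ch, ] <- exp(delta[ch] * A[ch, ]) * x[ch, ] + delta[ch] * Bt * vt[ch]
        out[ib, t, ch] <- sum(Ct * x[ch, ]) + params$D[ch] * vt[ch]
      }
    }
  }
  out
}

# direct rectangular-window periodogram band fractions (oracle for rPSD)
periodogram_band_fractions <- function(x, fs, bands = eeg_band_table()) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  p <- p[half]; freq <- freq[half]
  bp <- vapply(seq_len(nrow(bands)), function(j) {
    sum(p[freq >= bands$f_lo[j] & freq < bands$f_hi[j]])
  }, numeric(1))
  bp / sum(bp)
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
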