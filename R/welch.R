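#' Welch power spectral density estimate
#'
#' Averaged modified periodogram (Welch) estimate for one or more channels.
#' Each channel is cut into Hann-windowed segments of `nperseg` samples with
#' 50% overlap; segments are mean-detrended, and the one-sided density is
#' scaled so that `sum(psd) * df` approximates the signal variance
#' (Parseval).
#'
#' @param x Numeric vector, or a channels-by-samples matrix.
#' @param fs Sampling rate in Hz.
#' @param nperseg Samples per Welch segment. Default `min(2 * fs, n)`, i.e.
#'   2-second windows unless the input is shorter.
#' @return A list with `freq` (Hz, from 0 to Nyquist) and `psd`
#'   (channels x frequencies matrix, power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (is.null(nperseg)) nperseg <- min(round(2 * fs), n)
  nperseg <- as.integer(nperseg)
  stopifnot(nperseg >= 2L, nperseg <= n)
  hop <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = hop)
  win <- hann_window(nperseg)
  u <- sum(win^2)                       # window power normalisation
  nfreq <- nperseg %/% 2L + 1L
  freq <- (seq_len(nfreq) - 1L) * fs / nperseg
  psd <- matrix(0, nrow(x), nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nperseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, win, `*`)
    ft <- t(apply(seg, 1L, stats::fft))
    if (nrow(x) == 1L) ft <- matrix(ft, nrow = 1L)
    p <- (Mod(ft[, seq_len(nfreq), drop = FALSE])^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist when nperseg even)
    dbl <- rep(2, nfreq)
    dbl[1L] <- 1
    if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
    psd <- psd + sweep(p, 2L, dbl, `*`)
  }
  list(freq = freq, psd = psd / length(starts))
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) # periodic-agnostic symmetric Hann
}

#' Relative power spectral density features for one sub-segment
#'
#' Computes the Welch spectrum of every channel and integrates it over the
#' seven canonical bands (half-open intervals). Each band power is divided by
#' the total power over the union of band supports (1--45 Hz excluding the
#' 28--30 Hz gap), so rows sum to 1 for any channel with signal. A
#' zero-variance channel yields a zero row (guarded division) with a warning.
#'
#' @param x Channels-by-samples numeric matrix (one sub-segment).
#' @param fs Sampling rate in Hz; must exceed twice the top band edge.
#' @param bands Band table, defaulting to [eeg_band_table()].
#' @param relative If `FALSE`, return absolute band powers instead of
#'   relative ones (used by the feature-type ablation).
#' @param denominator `"band_union"` (default; rows sum to 1) or
#'   `"full_spectrum"` (divide by total power up to Nyquist).
#' @param nperseg Welch segment length forwarded to [welch_psd()].
#' @return Channels x 7 matrix of band features, columns named by band.
#' @export
compute_rpsd <- function(x, fs, bands = eeg_band_table(), relative = TRUE,
                         denominator = c("band_union", "full_spectrum"),
                         nperseg = NULL) {
  denominator <- match.arg(denominator)
  check_band_table(bands)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (fs <= 2 * max(bands$f_hi)) {
    stop(sprintf("sampling rate %g Hz too low for top band edge %g Hz", fs, max(bands$f_hi)),
         call. = FALSE)
  }
  w <- welch_psd(x, fs, nperseg = nperseg)
  nb <- nrow(bands)
  bp <- matrix(0, nrow(x), nb, dimnames = list(rownames(x), as.character(bands$band)))
  for (j in seq_len(nb)) {
    sel <- w$freq >= bands$f_lo[j] & w$freq < bands$f_hi[j]
    bp[, j] <- rowSums(w$psd[, sel, drop = FALSE]) * (w$freq[2L] - w$freq[1L])
  }
  if (!relative) return(bp)
  denom <- switch(denominator,
    band_union = rowSums(bp),
    full_spectrum = rowSums(w$psd) * (w$freq[2L] - w$freq[1L])
  )
  zero <- denom <= .Machine$double.eps
  if (any(zero)) {
    warning(sprintf("zero-variance channel(s) %s: returning zero feature row",
                    paste(which(zero), collapse = ", ")), call. = FALSE)
    denom[zero] <- 1
  }
  bp / denom
}
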