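#' Canonical EEG frequency band table
#'
#' The seven non-overlapping frequency bands used throughout the package:
#' delta (1--4 Hz), theta (4--8 Hz), alpha (8--12 Hz), low beta (12--16 Hz),
#' beta (16--20 Hz), high beta (20--28 Hz) and gamma (30--45 Hz). Band
#' intervals are half-open `[f_lo, f_hi)`, so shared edges are unambiguous,
#' and the 28--30 Hz gap between high beta and gamma carries no band.
#'
#' @return A tibble with columns `band` (ordered factor), `f_lo` and `f_hi`
#'   in Hz.
#' @export
#' @examples
#' eeg_band_table()
eeg_band_table <- function() {
  tibble::tibble(
    band = factor(
      c("delta", "theta", "alpha", "low_beta", "beta", "high_beta", "gamma"),
      levels = c("delta", "theta", "alpha", "low_beta", "beta", "high_beta", "gamma")
    ),
    f_lo = c(1, 4, 8, 12, 16, 20, 30),
    f_hi = c(4, 8, 12, 16, 20, 28, 45)
  )
}

# validate a user-supplied band table; returns it invisibly
check_band_table <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("band", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo >= bands$f_hi)) {
    stop("band table invalid: every f_lo must be < f_hi", call. = FALSE)
  }
  o <- order(bands$f_lo)
  if (any(bands$f_hi[o][-nrow(bands)] > bands$f_lo[o][-1] + 1e-12)) {
    stop("band table invalid: bands overlap", call. = FALSE)
  }
  invisible(bands)
}
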