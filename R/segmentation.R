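#' Segmentation configuration for two-level multi-scale windowing
#'
#' First-level segmentation cuts a trial into long overlapping windows
#' (default 20 s with a 4 s hop); second-level segmentation further divides
#' each long window with `K` shorter sliding windows, one per temporal
#' scale.
#'
#' @param l_s First-level window length in seconds (default 20).
#' @param s_s First-level hop in seconds (default 4).
#' @param scales List of `c(length_s, hop_s)` pairs, one per scale. Default
#'   three scales: 4/2 s, 8/4 s, 12/6 s.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(l_s = 20, s_s = 4,
                                scales = list(c(4, 2), c(8, 4), c(12, 6))) {
  stopifnot(l_s > 0, s_s > 0, s_s <= l_s, length(scales) >= 1)
  for (sc in scales) {
    stopifnot(length(sc) == 2)
    if (!(sc[2] > 0 && sc[2] <= sc[1] && sc[1] <= l_s)) {
      stop(sprintf("invalid scale (l'=%g, s'=%g): need 0 < s' <= l' <= l=%g",
                   sc[1], sc[2], l_s), call. = FALSE)
    }
  }
  structure(list(l_s = l_s, s_s = s_s, scales = scales),
            class = "segmentation_config")
}

#' Number of sliding windows of length `l` and hop `s` fitting in `n`
#' @noRd
n_windows <- function(n, l, s) {
  if (l > n) 0L else as.integer(floor((n - l) / s) + 1L)
}

#' First-level segmentation of a recording
#'
#' Slides a long window (length `cfg$l_s` s, hop `cfg$s_s` s) over the trial;
#' the trailing remainder that does not fill a window is discarded. Every
#' segment inherits the trial's label and provenance.
#'
#' @param rec A `raw_recording` (see [raw_recording()]).
#' @param cfg A [segmentation_config()].
#' @return List of channels-by-samples matrices, with attributes `label`,
#'   `subject_id`, `trial_id`, `segment_index`, `fs` on each element.
#' @export
segment_first_level <- function(rec, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cfg, "segmentation_config"))
  lw <- round(cfg$l_s * rec$fs)
  hop <- round(cfg$s_s * rec$fs)
  L <- ncol(rec$data)
  if (L < lw) {
    stop(sprintf("recording too short for first-level window: need %d samples (%g s at %g Hz), have %d",
                 lw, cfg$l_s, rec$fs, L), call. = FALSE)
  }
  n <- n_windows(L, lw, hop)
  lapply(seq_len(n), function(i) {
    a <- (i - 1L) * hop + 1L
    seg <- rec$data[, a:(a + lw - 1L), drop = FALSE]
    attr(seg, "label") <- rec$label
    attr(seg, "subject_id") <- rec$subject_id
    attr(seg, "trial_id") <- rec$trial_id
    attr(seg, "segment_index") <- i
    attr(seg, "fs") <- rec$fs
    seg
  })
}

#' Second-level segmentation of one first-level segment
#'
#' @param segment Channels-by-samples matrix (one first-level segment).
#' @param scale `c(length_s, hop_s)` in seconds.
#' @param fs Sampling rate in Hz.
#' @return List of channels-by-samples sub-segment matrices.
#' @export
segment_second_level <- function(segment, scale, fs) {
  lw <- round(scale[1] * fs)
  hop <- round(scale[2] * fs)
  n <- ncol(segment)
  if (lw > n) {
    stop(sprintf("sub-window of %g s (%d samples) exceeds segment length %d samples",
                 scale[1], lw, n), call. = FALSE)
  }
  lapply(seq_len(n_windows(n, lw, hop)), function(i) {
    a <- (i - 1L) * hop + 1L
    segment[, a:(a + lw - 1L), drop = FALSE]
  })
}

#' Build per-scale relative-PSD feature tensors
#'
#' For each temporal scale `k`, every first-level segment is divided into
#' `n_k` sub-segments whose per-channel 7-band relative PSD rows are stacked
#' into a tensor of shape `(b, n_k, c, 7)` where `b` is the number of
#' first-level segments in the batch.
#'
#' @param segments List of first-level segments (all with the same channel
#'   count and sampling rate), as produced by [segment_first_level()].
#' @param cfg A [segmentation_config()].
#' @param fs Sampling rate in Hz (taken from segment attributes if present).
#' @param bands Band table.
#' @param feature_type `"rpsd"` (default), `"psd"` (absolute band power) or
#'   `"de"` (differential entropy, `0.5 * log(2 * pi * e * band power)`).
#' @return A list with one element per scale: list of `values` (4-D array
#'   `(b, n_k, c, f)`), `scale` (the `c(l', s')` pair), `n_k`, and `meta`
#'   (tibble of per-segment provenance).
#' @export
build_feature_tensors <- function(segments, cfg = segmentation_config(), fs = NULL,
                                  bands = eeg_band_table(),
                                  feature_type = c("rpsd", "psd", "de")) {
  feature_type <- match.arg(feature_type)
  stopifnot(length(segments) >= 1)
  cc <- vapply(segments, nrow, integer(1))
  if (length(unique(cc)) != 1L) {
    stop("heterogeneous channel counts across segments: ",
         paste(unique(cc), collapse = ", "), call. = FALSE)
  }
  if (is.null(fs)) fs <- attr(segments[[1L]], "fs")
  stopifnot(!is.null(fs))
  b <- length(segments)
  c_ <- cc[1L]
  f <- nrow(bands)
  meta <- tibble::tibble(
    segment = seq_len(b),
    subject_id = vapply(segments, function(s) as.character(attr(s, "subject_id") %||% NA_character_), character(1)),
    trial_id = vapply(segments, function(s) as.character(attr(s, "trial_id") %||% NA_character_), character(1)),
    label = vapply(segments, function(s) as.character(attr(s, "label") %||% NA_character_), character(1))
  )
  lapply(seq_along(cfg$scales), function(k) {
    scale <- cfg$scales[[k]]
    n_k <- n_windows(ncol(segments[[1L]]), round(scale[1] * fs), round(scale[2] * fs))
    vals <- array(0, dim = c(b, n_k, c_, f))
    for (i in seq_len(b)) {
      subs <- segment_second_level(segments[[i]], scale, fs)
      for (j in seq_len(n_k)) {
        m <- switch(feature_type,
          rpsd = compute_rpsd(subs[[j]], fs, bands),
          psd = compute_rpsd(subs[[j]], fs, bands, relative = FALSE),
          de = 0.5 * log(2 * pi * exp(1) *
                 pmax(compute_rpsd(subs[[j]], fs, bands, relative = FALSE), 1e-12))
        )
        vals[i, j, , ] <- m
      }
    }
    list(values = vals, scale = scale, k = k, n_k = n_k, meta = meta)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
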