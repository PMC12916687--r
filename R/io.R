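# Delimited recording format: channels-as-rows CSV plus a JSON sidecar
# carrying sampling rate, channel labels and provenance. A dataset manifest
# is a CSV of (subject_id, trial_id, label, path).

#' Write a recording as a delimited matrix with a JSON sidecar
#'
#' @param rec A [raw_recording()].
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording_delimited <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         subject_id = rec$subject_id, trial_id = rec$trial_id, label = rec$label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from any supported format
#'
#' @param path File path. Format is inferred from the extension (`.edf` or
#'   delimited with `<path>.json` sidecar) unless given explicitly.
#' @param format `"edf"` or `"delimited"`.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") return(read_edf(path))
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar missing sampling rate 'fs': ", side, call. = FALSE)
  data <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(data) <- NULL
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    labs <- meta$channel_labels %||% as.character(bad)
    stop("non-finite samples in channel(s): ",
         paste(labs[bad], collapse = ", "), call. = FALSE)
  }
  raw_recording(data, meta$fs, meta$channel_labels,
                subject_id = meta$subject_id %||% NA,
                trial_id = meta$trial_id %||% NA,
                label = meta$label %||% NA)
}

#' Write a dataset (recordings + manifest) to a directory
#'
#' @param dataset As returned by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param format `"delimited"` (default) or `"edf"`.
#' @return Tibble manifest with a `path` column; also written as
#'   `manifest.csv` inside `dir`.
#' @export
write_dataset <- function(dataset, dir, format = c("delimited", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") "edf" else "csv"
  manifest <- dataset$manifest
  manifest$path <- file.path(dir, sprintf("s%02d_t%02d.%s",
                                          as.integer(manifest$subject_id),
                                          as.integer(manifest$trial_id), ext))
  for (i in seq_along(dataset$recordings)) {
    if (format == "edf") write_edf(dataset$recordings[[i]], manifest$path[i])
    else write_recording_delimited(dataset$recordings[[i]], manifest$path[i])
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset back from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` with columns subject_id,
#'   trial_id, label, path.
#' @return A list with `recordings` and `manifest`, as [generate_dataset()].
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("no such manifest: ", manifest_path, call. = FALSE)
  }
  manifest <- tibble::as_tibble(utils::read.csv(manifest_path))
  base <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    rec <- read_recording(p)
    rec$subject_id <- manifest$subject_id[i]
    rec$trial_id <- manifest$trial_id[i]
    rec$label <- manifest$label[i]
    rec
  })
  list(recordings = recs, manifest = manifest)
}

#' Export a channel graph as a symmetric edge list
#'
#' @param W Symmetric adjacency matrix with channel labels as dimnames (or
#'   labels supplied via `labels`).
#' @param labels Optional channel labels.
#' @param keep_zero Keep zero-weight pairs too (default drops them).
#' @return Tibble with columns `ch_i`, `ch_j`, `weight` (upper triangle).
#' @export
graph_edge_list <- function(W, labels = rownames(W), keep_zero = FALSE) {
  c_ <- nrow(W)
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(c_))
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- tibble::tibble(
    ch_i = labels[idx[, 1L]], ch_j = labels[idx[, 2L]],
    weight = W[idx]
  )
  if (!keep_zero) out <- dplyr::filter(out, .data$weight != 0)
  out
}
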