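# Scalp region maps: channel label -> region id. Bundled partitions follow
# standard 10-20 lobe anatomy (prefrontal/frontal, frontocentral, central,
# temporal, centroparietal, parietal, occipital and finer left/right splits)
# and ship as editable JSON under extdata/region_maps; they are
# configuration, not hard-coded anatomy.

#' Load a scalp region map
#'
#' @param name Either a bundled partition name (`"62ch-7region"`,
#'   `"62ch-10region"`, `"62ch-17region"`, `"32ch-default"`) or a path to a
#'   JSON file of the form `{channel_label: region_id}`.
#' @return Named integer vector mapping channel label to region id, with the
#'   partition name as attribute `partition`.
#' @export
region_map <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "region_maps", paste0(name, ".json"), package = "msgm")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown region partition: ", name, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- stats::setNames(as.integer(unlist(raw)), names(raw))
  check_region_map(map)
  attr(map, "partition") <- sub("\\.json$", "", basename(path))
  map
}

check_region_map <- function(map, channel_labels = NULL) {
  stopifnot(!is.null(names(map)), !anyDuplicated(names(map)))
  ids <- sort(unique(as.integer(map)))
  if (!identical(ids, seq_along(ids))) {
    stop("region ids must be contiguous integers starting at 1", call. = FALSE)
  }
  if (!is.null(channel_labels)) {
    missing <- setdiff(channel_labels, names(map))
    if (length(missing)) {
      stop("channels without a region assignment: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(map)
}

#' Same-region indicator matrix for a set of channels
#'
#' @param channel_labels Channel labels, in matrix order.
#' @param map Named region map covering all labels.
#' @return `c x c` logical matrix, `TRUE` where two channels share a region.
#' @export
region_mask <- function(channel_labels, map) {
  check_region_map(map, channel_labels)
  r <- map[channel_labels]
  outer(r, r, `==`)
}
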