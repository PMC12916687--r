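# YAML pipeline configuration: one document merging simulation,
# segmentation, feature, graph, model, training and protocol sections.
# Unknown keys are rejected; defaults follow the reference hyperparameter
# tables (learning rate 3e-4, batch 32, h = 32, d_state = 16, kernel 4,
# one temporal block) and are filled for any key a file omits.

#' Default pipeline configuration
#'
#' @return Nested named list of all pipeline settings.
#' @export
default_config <- function() {
  list(
    simulation = list(
      n_subjects = 8L, trials_per_subject = 8L, c = 8L, fs = 128,
      duration_s = 30, classes = c("negative", "positive"),
      effect_band = "alpha", effect_size = 1.0, n_regions = 2L,
      within_region_corr = 0.6, noise_exponent = 1, subject_gain_sd = 0.2,
      amplitude_uv = 20, seed = 1L
    ),
    segmentation = list(l_s = 20, s_s = 4,
                        scales = list(c(4, 2), c(8, 4), c(12, 6))),
    features = list(type = "rpsd", denominator = "band_union"),
    graph = list(region_partition = NULL),
    model = list(h = 32L, w_out = 16L, cheb_order = 3L, gcn_depths = c(1L, 2L),
                 m_blocks = 1L, d_state = 16L, expansion = 2L,
                 conv_kernel = 4L, dropout = 0.25, d_out = 2L),
    training = list(lr = 3e-4, weight_decay = 0.01, label_smoothing = 0.1,
                    batch_size = 32L, max_epochs = 30L, patience = 5L,
                    seed = 1L),
    protocol = list(type = "loso", n = 1L, val_fraction = NULL),
    ablation = "none"
  )
}

merge_checked <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste(path, key, sep = ".") else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", here, call. = FALSE)
    }
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.null(uv)) next                  # empty section: keep defaults
    if (is.list(dv) && !is.null(names(dv)) && length(names(dv))) {
      if (!is.list(uv)) stop("type mismatch at ", here, ": expected a section",
                             call. = FALSE)
      defaults[[key]] <- merge_checked(dv, uv, here)
    } else {
      defaults[[key]] <- uv
    }
  }
  defaults
}

normalize_config <- function(cfg) {
  cfg$segmentation$scales <- lapply(cfg$segmentation$scales, as.numeric)
  cfg$model$gcn_depths <- as.integer(unlist(cfg$model$gcn_depths))
  cfg$simulation$classes <- as.character(unlist(cfg$simulation$classes))
  # canonical shape for sections whose NULL-valued keys YAML may drop
  cfg$graph <- list(region_partition = cfg$graph$region_partition)
  cfg$protocol <- list(type = cfg$protocol$type %||% "loso",
                       n = cfg$protocol$n %||% 1L,
                       val_fraction = cfg$protocol$val_fraction)
  cfg
}

validate_config <- function(cfg) {
  # constructors run all the invariant checks
  do.call(segmentation_config, cfg$segmentation)
  model_config(h = cfg$model$h, w_out = cfg$model$w_out,
               cheb_order = cfg$model$cheb_order,
               gcn_depths = cfg$model$gcn_depths,
               m_blocks = cfg$model$m_blocks, d_state = cfg$model$d_state,
               expansion = cfg$model$expansion,
               conv_kernel = cfg$model$conv_kernel,
               dropout = cfg$model$dropout, d_out = cfg$model$d_out,
               feature_type = cfg$features$type, ablation = cfg$ablation)
  if (!cfg$protocol$type %in% c("loso", "leave_n_out")) {
    stop("protocol.type must be 'loso' or 'leave_n_out'", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys are filled from [default_config()]; unknown keys and
#' invariant violations (e.g. hop exceeding window length) are errors. An
#' empty file yields the full defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_checked(cfg, user)
  }
  cfg <- normalize_config(cfg)
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# FNV-1a hash of the canonical YAML serialisation; stamps artifacts so any
# output can be traced to the exact configuration that produced it
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(yaml::as.yaml(cfg), collapse = "\n"))
  h <- 216613626
  for (b in bytes) h <- ((h + b) * 16777619) %% 2147483647
  sprintf("%08x", h)
}
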