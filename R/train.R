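# Subject-independent training and evaluation: leave-one-subject-out /
# leave-n-subject-out fold plans, an AdamW training loop with label-smoothed
# cross-entropy and early stopping on validation accuracy, and per-fold
# accuracy / macro-F1 reporting.

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW at learning rate
#' 3e-4, label smoothing 0.1, batch size 32, early-stopping patience 5 on
#' validation accuracy.
#'
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param label_smoothing Label smoothing coefficient.
#' @param batch_size Mini-batch size.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stopping patience (epochs without val improvement).
#' @param seed RNG seed for init, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 3e-4, weight_decay = 0.01, label_smoothing = 0.1,
                         batch_size = 32L, max_epochs = 30L, patience = 5L,
                         seed = 1L) {
  structure(list(lr = lr, weight_decay = weight_decay,
                 label_smoothing = label_smoothing,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-level cross-validation fold plan
#'
#' LOSO: one fold per subject; the remaining subjects are split into
#' training and validation sets by subject at the given ratio (default
#' 8:2). Leave-n-out: subjects are shuffled (seeded) into `ceiling(S / n)`
#' test groups; the remainder is split 9:1 by default.
#'
#' @param subject_ids Vector of subject identifiers.
#' @param protocol `"loso"` or `"leave_n_out"`.
#' @param n Test-group size for leave-n-out (e.g. 8 or 12).
#' @param val_fraction Fraction of non-test subjects used for validation
#'   (defaults 0.2 for LOSO, 0.1 for leave-n-out).
#' @param seed Seed for the subject shuffles.
#' @return Tibble with columns `fold`, `test`, `train`, `val` (list-cols of
#'   subject ids) and attribute `protocol`.
#' @export
make_folds <- function(subject_ids, protocol = c("loso", "leave_n_out"),
                       n = 1L, val_fraction = NULL, seed = 1L) {
  protocol <- match.arg(protocol)
  subjects <- unique(subject_ids)
  S <- length(subjects)
  if (S < 2) stop("need at least 2 subjects", call. = FALSE)
  if (is.null(val_fraction)) val_fraction <- if (protocol == "loso") 0.2 else 0.1
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  test_groups <- if (protocol == "loso") {
    as.list(subjects)
  } else {
    if (n >= S) stop("leave-n-out requires n < number of subjects", call. = FALSE)
    shuffled <- sample(subjects)
    split(shuffled, ceiling(seq_along(shuffled) / n))
  }
  rows <- lapply(seq_along(test_groups), function(i) {
    test <- test_groups[[i]]
    rest <- sample(setdiff(subjects, test))
    n_val <- max(1L, round(val_fraction * length(rest)))
    tibble::tibble(fold = i, test = list(test),
                   val = list(rest[seq_len(n_val)]),
                   train = list(rest[-seq_len(n_val)]))
  })
  out <- dplyr::bind_rows(rows)[, c("fold", "test", "train", "val")]
  attr(out, "protocol") <- protocol
  out
}

#' Binarize a valence score at the 3.0 threshold
#'
#' Scores above 3.0 map to `"high"`, below to `"low"`; exact 3.0 is
#' excluded (returns `NA` with a warning) rather than assigned to either
#' class.
#'
#' @param score Numeric vector of valence self-reports.
#' @return Character vector of `"high"` / `"low"` / `NA`.
#' @export
binarize_valence <- function(score) {
  if (!is.numeric(score)) stop("valence scores must be numeric", call. = FALSE)
  out <- ifelse(score > 3, "high", ifelse(score < 3, "low", NA_character_))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " score(s) exactly at the 3.0 threshold excluded",
            call. = FALSE)
  }
  out
}

#' Segment a dataset and compute per-scale feature tensors
#'
#' @param dataset List with `recordings` (and optionally `manifest`).
#' @param seg_cfg A [segmentation_config()].
#' @param feature_type Forwarded to [build_feature_tensors()].
#' @return List: `tensors` (per scale, `(B, n_k, c, f)` over all first-level
#'   segments), `meta` (tibble with subject_id, label per segment),
#'   `channel_labels`, `fs`.
#' @export
prepare_features <- function(dataset, seg_cfg = segmentation_config(),
                             feature_type = "rpsd") {
  segs <- unlist(lapply(dataset$recordings, segment_first_level, cfg = seg_cfg),
                 recursive = FALSE)
  fs <- dataset$recordings[[1L]]$fs
  tens <- build_feature_tensors(segs, seg_cfg, fs = fs, feature_type = feature_type)
  list(tensors = tens, meta = tens[[1L]]$meta,
       channel_labels = dataset$recordings[[1L]]$channel_labels, fs = fs)
}

# ---- metrics ----------------------------------------------------------------

macro_f1 <- function(truth, pred, classes) {
  f1s <- vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1s)
}

# ---- optimizer --------------------------------------------------------------

adamw_state <- function(flat) {
  list(m = lapply(flat, function(p) p * 0), v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(flat, grads, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    upd <- (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    flat[[k]] <- flat[[k]] - lr * (upd + wd * flat[[k]])
  }
  list(flat = flat, state = state)
}

# write flat parameter values back into the nested structure
unflatten_params <- function(params, flat, prefix = NULL) {
  nm <- names(params)
  if (is.null(nm)) nm <- as.character(seq_along(params))
  for (i in seq_along(params)) {
    key <- if (is.null(prefix)) nm[i] else paste(prefix, nm[i], sep = ".")
    el <- params[[i]]
    if (is.list(el)) params[[i]] <- unflatten_params(el, flat, key)
    else if (!is.null(flat[[key]])) params[[i]] <- flat[[key]]
  }
  params
}

# ---- prediction -------------------------------------------------------------

predict_msgm <- function(params, config, F_list, region_mask, graphs,
                         batch_size = 64L) {
  B <- dim(F_list[[1L]])[1L]
  preds <- integer(B)
  probs <- NULL
  for (start in seq(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    Fb <- lapply(F_list, function(F) F[idx, , , , drop = FALSE])
    tape <- ad_tape()
    reg <- new.env(parent = emptyenv())
    pn <- params_to_nodes(tape, params, reg)
    fw <- msgm_forward(tape, pn, Fb, config, region_mask, graphs = graphs,
                       training = FALSE)
    L <- fw$logits$value
    preds[idx] <- max.col(L, ties.method = "first")
    probs <- rbind(probs, exp(L - apply(L, 1, max)) /
                     rowSums(exp(L - apply(L, 1, max))))
  }
  list(class = preds, prob = probs)
}

# ---- training loop ----------------------------------------------------------

#' Train and evaluate the model over a subject-independent fold plan
#'
#' Per fold: parameters are (re)initialised from the seed, mini-batches are
#' drawn from the training subjects' segments, graphs are rebuilt per batch
#' from the current transform parameters, and AdamW minimises label-smoothed
#' cross-entropy. After each epoch validation accuracy is measured with the
#' graphs frozen at the last training state; the best-validation snapshot is
#' restored for testing and early stopping uses the configured patience.
#'
#' @param features From [prepare_features()].
#' @param folds From [make_folds()].
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @param region_map Named region map covering the channel labels (or a
#'   logical mask).
#' @param classes Class labels in order (defaults to sorted unique labels).
#' @param scales Scale definitions (for bookkeeping; taken from features).
#' @param verbose Print per-fold progress.
#' @return An object of class `msgm_fit`: per-fold metrics tibble, config,
#'   final-fold parameters and frozen graphs, diagnostics log.
#' @export
train_msgm <- function(features, folds, config = model_config(),
                       tc = train_config(), region_map = NULL,
                       classes = NULL, scales = NULL, verbose = FALSE) {
  meta <- features$meta
  if (is.null(classes)) classes <- sort(unique(meta$label))
  stopifnot(length(classes) == config$d_out)
  y_all <- match(meta$label, classes)
  tensors <- features$tensors
  if (config$ablation == "no_temporal_multiscale") {
    lens <- vapply(tensors, function(t) t$scale[1L], numeric(1))
    tensors <- tensors[which.max(lens)]
  }
  F_all <- lapply(tensors, `[[`, "values")
  n_ks <- vapply(tensors, `[[`, integer(1), "n_k")
  c_ <- dim(F_all[[1L]])[3L]
  mask <- if (is.matrix(region_map) && is.logical(region_map)) region_map
          else if (is.null(region_map)) matrix(TRUE, c_, c_)
          else region_mask(features$channel_labels, region_map)

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  fold_rows <- list()
  diag_log <- list()
  last_state <- NULL
  for (fi in seq_len(nrow(folds))) {
    set.seed(tc$seed + 1000L * fi)
    test_sub <- folds$test[[fi]]
    train_sub <- folds$train[[fi]]
    val_sub <- folds$val[[fi]]
    idx_train <- which(meta$subject_id %in% as.character(train_sub))
    idx_val <- which(meta$subject_id %in% as.character(val_sub))
    idx_test <- which(meta$subject_id %in% as.character(test_sub))
    stopifnot(length(intersect(idx_test, c(idx_train, idx_val))) == 0)

    params <- init_msgm_params(config, n_ks, c_)
    flat <- flatten_params(params)
    opt <- adamw_state(flat)
    best <- list(acc = -Inf, flat = flat, graphs = NULL, epoch = 0L)
    wait <- 0L
    graphs_now <- NULL
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample(idx_train)
      for (start in seq(1L, length(ord), by = tc$batch_size)) {
        bidx <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
        if (length(bidx) < 2L) next
        Fb <- lapply(F_all, function(F) F[bidx, , , , drop = FALSE])
        tape <- ad_tape()
        reg <- new.env(parent = emptyenv())
        pn <- params_to_nodes(tape, params, reg)
        fw <- msgm_forward(tape, pn, Fb, config, mask, graphs = NULL,
                           training = TRUE)
        loss <- ad_ce_loss(fw$logits, y_all[bidx], tc$label_smoothing)
        if (!is.finite(loss$value)) {
          stop(sprintf("non-finite loss in fold %d epoch %d: training aborted",
                       fi, epoch), call. = FALSE)
        }
        grads_all <- ad_backward(loss)
        grads <- list()
        for (key in ls(reg)) grads[[key]] <- grads_all[[reg[[key]]]]
        stepped <- adamw_step(flat, grads, opt, tc$lr, tc$weight_decay)
        flat <- stepped$flat
        opt <- stepped$state
        params <- unflatten_params(params, flat)
        graphs_now <- fw$graphs
        if (!is.null(fw$diagnostics)) {
          diag_log[[length(diag_log) + 1L]] <-
            dplyr::mutate(fw$diagnostics, fold = fi, epoch = epoch)
        }
      }
      Fv <- lapply(F_all, function(F) F[idx_val, , , , drop = FALSE])
      pv <- predict_msgm(params, config, Fv, mask, graphs_now)
      val_acc <- mean(pv$class == y_all[idx_val])
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, flat = flat, graphs = graphs_now,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) break
      }
    }
    params <- unflatten_params(params, best$flat)
    Ft <- lapply(F_all, function(F) F[idx_test, , , , drop = FALSE])
    pt <- predict_msgm(params, config, Ft, mask, best$graphs)
    truth <- y_all[idx_test]
    acc <- mean(pt$class == truth)
    f1 <- macro_f1(truth, pt$class, seq_along(classes))
    fold_rows[[fi]] <- tibble::tibble(
      fold = fi, test_subjects = paste(test_sub, collapse = ","),
      n_test = length(idx_test), accuracy = 100 * acc, f1 = 100 * f1,
      best_epoch = best$epoch, val_accuracy = 100 * best$acc)
    last_state <- list(params = params, graphs = best$graphs)
    if (verbose) {
      message(sprintf("fold %d/%d: test acc %.1f%% (val %.1f%%, epoch %d)",
                      fi, nrow(folds), 100 * acc, 100 * best$acc, best$epoch))
    }
  }
  structure(list(
    folds = dplyr::bind_rows(fold_rows),
    config = config, train_config = tc, classes = classes,
    params = last_state$params, graphs = last_state$graphs,
    diagnostics = if (length(diag_log)) dplyr::bind_rows(diag_log) else NULL,
    n_parameters = count_parameters(init_msgm_params(config, n_ks, c_))
  ), class = "msgm_fit")
}

#' @export
print.msgm_fit <- function(x, ...) {
  cat(sprintf("<msgm_fit> %d folds | accuracy %.2f +/- %.2f %% | macro-F1 %.2f +/- %.2f %%\n",
              nrow(x$folds), mean(x$folds$accuracy), stats::sd(x$folds$accuracy),
              mean(x$folds$f1), stats::sd(x$folds$f1)))
  invisible(x)
}
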