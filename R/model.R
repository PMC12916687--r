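# End-to-end model assembly: per-scale graph priors -> four Chebyshev
# encoders + base embedding -> fused global/local token sequences -> shared
# selective state-space stack -> pooled, L2-normalised, scale-averaged
# embedding -> linear classifier. The forward pass is built on the autodiff
# tape so the same code serves training (with gradients) and inference.

MSGM_ABLATIONS <- c("none", "no_temporal_multiscale", "no_spatial_multiscale",
                    "single_gcn", "no_fusion", "no_mamba")

#' Model configuration
#'
#' Defaults follow the reference architecture: hidden width `h = 32`, one
#' temporal block, Chebyshev encoders of depth 1 (shallow) and 2 (deep),
#' state dimension 16, `dt_rank = ceiling(h / 16)`, convolution kernel 4,
#' dropout 0.25.
#'
#' @param h Token embedding width.
#' @param w_out Chebyshev encoder output width per node.
#' @param cheb_order Number of Chebyshev polynomial terms `I`.
#' @param gcn_depths Depths of the two encoders per stream, `c(1, 2)`.
#' @param m_blocks Number of temporal blocks `M`.
#' @param d_state Selective-SSM state dimension.
#' @param expansion Block width expansion factor.
#' @param conv_kernel Causal depthwise convolution kernel.
#' @param dropout Dropout rate on block outputs (training only).
#' @param d_out Number of classes.
#' @param feature_type `"rpsd"`, `"psd"` or `"de"`.
#' @param ablation One of `r paste(MSGM_ABLATIONS, collapse = ", ")`.
#' @return A `model_config` list.
#' @export
model_config <- function(h = 32L, w_out = 16L, cheb_order = 3L,
                         gcn_depths = c(1L, 2L), m_blocks = 1L,
                         d_state = 16L, expansion = 2L, conv_kernel = 4L,
                         dropout = 0.25, d_out = 2L,
                         feature_type = c("rpsd", "psd", "de"),
                         ablation = "none") {
  feature_type <- match.arg(feature_type)
  ablation <- match.arg(ablation, MSGM_ABLATIONS)
  stopifnot(h >= 1, w_out >= 1, cheb_order >= 1, m_blocks >= 1,
            d_state >= 1, conv_kernel >= 1, dropout >= 0, dropout < 1, d_out >= 2)
  structure(list(h = as.integer(h), w_out = as.integer(w_out),
                 cheb_order = as.integer(cheb_order),
                 gcn_depths = as.integer(gcn_depths),
                 m_blocks = as.integer(m_blocks), d_state = as.integer(d_state),
                 expansion = as.integer(expansion),
                 conv_kernel = as.integer(conv_kernel), dropout = dropout,
                 d_out = as.integer(d_out), feature_type = feature_type,
                 dt_rank = as.integer(ceiling(h / 16)), ablation = ablation),
            class = "model_config")
}

#' Apply a single ablation switch to a configuration
#'
#' `no_temporal_multiscale` keeps only the longest window scale;
#' `no_spatial_multiscale` uses the global graph for both streams;
#' `single_gcn` replaces the shallow/deep encoder pair with one depth-1
#' encoder per stream; `no_fusion` feeds the base embedding straight to the
#' temporal stack; `no_mamba` replaces the temporal stack by the identity.
#'
#' @param config A [model_config()].
#' @param flag One ablation flag.
#' @return The modified configuration.
#' @export
ablate <- function(config, flag) {
  flag <- match.arg(flag, MSGM_ABLATIONS)
  if (config$ablation != "none" && flag != "none" && flag != config$ablation) {
    stop("conflicting ablation flags: ", config$ablation, " and ", flag, call. = FALSE)
  }
  config$ablation <- flag
  config
}

# scales actually used given the ablation
active_scales <- function(scales, ablation) {
  if (ablation == "no_temporal_multiscale") {
    lengths <- vapply(scales, `[`, numeric(1), 1L)
    scales[which.max(lengths)]
  } else scales
}

#' Initialise all trainable parameters
#'
#' @param config A [model_config()].
#' @param n_ks Integer vector of sub-segment counts per active scale.
#' @param c Channel count.
#' @param f Band count (7).
#' @return Nested named list of parameter arrays.
#' @export
init_msgm_params <- function(config, n_ks, c, f = 7L) {
  K <- length(n_ks)
  use_enc <- config$ablation != "no_fusion"
  single <- config$ablation == "single_gcn"
  scales <- lapply(seq_len(K), function(k) {
    n_k <- n_ks[k]
    sc <- list(trans = transform_params(c, n_k, f))
    if (use_enc) {
      mk_stream <- function() {
        if (single) {
          list(sh = cheb_encoder_params(f, config$w_out, config$cheb_order, 1L))
        } else {
          list(sh = cheb_encoder_params(f, config$w_out, config$cheb_order,
                                        config$gcn_depths[1L]),
               dp = cheb_encoder_params(f, config$w_out, config$cheb_order,
                                        config$gcn_depths[2L]))
        }
      }
      sc$enc_g <- mk_stream()
      sc$enc_l <- mk_stream()
      sc$head_g <- list(W = xavier_uniform(c * config$w_out, config$h),
                        b = rep(0, config$h))
      sc$head_l <- list(W = xavier_uniform(c * config$w_out, config$h),
                        b = rep(0, config$h))
    }
    sc$base <- list(W = xavier_uniform(c * f, config$h), b = rep(0, config$h))
    sc
  })
  out <- list(scales = scales)
  if (config$ablation != "no_mamba") {
    out$blocks <- lapply(seq_len(config$m_blocks), function(m) {
      mamba_block_params(config$h, config$expansion, config$d_state,
                         config$conv_kernel)
    })
    out$final_gain <- rep(1, config$h)
  }
  out$clf <- list(W = xavier_uniform(config$h, config$d_out),
                  b = rep(0, config$d_out))
  out
}

#' Count trainable parameters
#'
#' @param params From [init_msgm_params()].
#' @return Integer total of array elements across all parameter leaves.
#' @export
count_parameters <- function(params) {
  leaves <- flatten_params(params)
  sum(vapply(leaves, length, numeric(1)))
}

# nested parameter list -> flat named list of arrays (path-joined names);
# integer scalars (d_state, dt_rank, ...) are metadata, not parameters
flatten_params <- function(x, prefix = NULL) {
  out <- list()
  nm <- names(x)
  if (is.null(nm)) nm <- as.character(seq_along(x))
  for (i in seq_along(x)) {
    key <- if (is.null(prefix)) nm[i] else paste(prefix, nm[i], sep = ".")
    el <- x[[i]]
    if (is.list(el)) out <- c(out, flatten_params(el, key))
    else if (is.numeric(el) && !(is.integer(el) && length(el) == 1L)) out[[key]] <- el
  }
  out
}

# mirror a nested parameter list into tape nodes; registry maps path -> id
params_to_nodes <- function(tape, params, registry, prefix = NULL) {
  nm <- names(params)
  if (is.null(nm)) nm <- as.character(seq_along(params))
  out <- vector("list", length(params))
  names(out) <- nm
  for (i in seq_along(params)) {
    key <- if (is.null(prefix)) nm[i] else paste(prefix, nm[i], sep = ".")
    el <- params[[i]]
    if (is.list(el)) {
      out[[i]] <- params_to_nodes(tape, el, registry, key)
    } else if (is.numeric(el) && !(is.integer(el) && length(el) <= 1)) {
      node <- ad_in(tape, el)
      registry[[key]] <- node$id
      out[[i]] <- node
    } else {
      out[[i]] <- el
    }
  }
  out
}

# ---- layout helpers for the tape forward ------------------------------------

# (b, n, c, f) -> channel-major layout A (c, S*f), S = b*n, s = (b-1)*n + t
to_layout_A <- function(F) {
  d <- dim(F)
  matrix(aperm(F, c(3L, 4L, 2L, 1L)), d[3])
}
rearr_A_to_B <- function(c_, S, w) {
  list(fwd = function(m) matrix(aperm(array(m, c(c_, w, S)), c(1L, 3L, 2L)), c_ * S, w),
       bwd = function(m) matrix(aperm(array(m, c(c_, S, w)), c(1L, 3L, 2L)), c_, w * S))
}
rearr_B_to_A <- function(c_, S, w) {
  r <- rearr_A_to_B(c_, S, w)
  list(fwd = r$bwd, bwd = r$fwd)
}
# layout B (S*c, w) -> token rows (S, c*w)
rearr_B_to_tokens <- function(c_, S, w) {
  list(fwd = function(m) t(matrix(aperm(array(m, c(c_, S, w)), c(3L, 1L, 2L)), w * c_, S)),
       bwd = function(m) matrix(aperm(array(t(m), c(w, c_, S)), c(2L, 3L, 1L)), c_ * S, w))
}

# tape Chebyshev encoder on layout-A input; returns token-row node (S, c*w_out)
tape_cheb_encoder <- function(xA, Lhat, layers, c_, S) {
  order <- length(layers[[1L]]$theta)
  # Chebyshev basis as tape nodes (shared recurrence)
  Ts <- vector("list", order)
  Ts[[1L]] <- ad_in(xA$tape, diag(c_))
  if (order >= 2L) Ts[[2L]] <- Lhat
  if (order >= 3L) {
    for (i in 3:order) {
      Ts[[i]] <- ad_sub(ad_scale(ad_matmul(Lhat, Ts[[i - 1L]]), 2), Ts[[i - 2L]])
    }
  }
  x <- xA
  w_in <- ncol(xA$value) / S
  for (l in seq_along(layers)) {
    layer <- layers[[l]]
    w_out <- ncol(layer$theta[[1L]]$value)
    AB <- rearr_A_to_B(c_, S, w_in)
    acc <- NULL
    for (i in seq_len(order)) {
      term <- ad_matmul(ad_rearrange(ad_matmul(Ts[[i]], x), AB$fwd, AB$bwd),
                        layer$theta[[i]])
      acc <- if (is.null(acc)) term else ad_add(acc, term)
    }
    x <- ad_relu(ad_sub_rowvec(acc, layer$bias))   # layout B (S*c, w_out)
    w_in <- w_out
    if (l < length(layers)) {
      BA <- rearr_B_to_A(c_, S, w_out)
      x <- ad_rearrange(x, BA$fwd, BA$bwd)    # back to layout A for next layer
    }
  }
  Btok <- rearr_B_to_tokens(c_, S, w_in)
  ad_rearrange(x, Btok$fwd, Btok$bwd)
}

# tape version of one temporal block + residual; returns list(node, steps)
tape_mamba_block <- function(x, blk, b, n, dropout_mask = NULL) {
  S <- b * n
  di <- ncol(blk$W_in_a$value)
  K <- ncol(blk$conv_w$value)
  xn <- ad_rmsnorm(x, blk$gain)
  pa <- ad_add_rowvec(ad_matmul(xn, blk$W_in_a), blk$b_in_a)
  # causal depthwise conv: shift within each length-n sequence
  tok_t <- rep(seq_len(n), times = b)         # token position of each row
  u <- NULL
  for (lag in 0:(K - 1L)) {
    src <- pmax(seq_len(S) - lag, 1L)
    valid <- as.numeric(tok_t - lag >= 1L)
    col <- ad_cols(blk$conv_w, K - lag)
    term <- ad_mulc(ad_mul_rowvec(ad_rows(pa, src), col), matrix(valid, S, di))
    u <- if (is.null(u)) term else ad_add(u, term)
  }
  v <- ad_silu(ad_add_rowvec(u, blk$conv_b))
  # input-dependent SSM parameters
  ssm <- blk$ssm
  ds <- ssm$d_state; dtr <- ssm$dt_rank
  Z <- ad_matmul(v, ssm$W_x)
  Delta <- ad_softplus(ad_add_rowvec(ad_matmul(ad_cols(Z, seq_len(dtr)), ssm$W_dt),
                                     ssm$b_dt))
  Bm <- ad_cols(Z, dtr + seq_len(ds))
  Cm <- ad_cols(Z, dtr + ds + seq_len(ds))
  A <- ad_negexp(ssm$A_log)
  state <- ad_in(x$tape, array(0, c(b, di, ds)))
  ys <- vector("list", n)
  idx_list <- vector("list", n)
  for (t in seq_len(n)) {
    idx <- (seq_len(b) - 1L) * n + t
    idx_list[[t]] <- idx
    dt_t <- ad_rows(Delta, idx)
    v_t <- ad_rows(v, idx)
    dA <- ad_exp(ad_outer_bA(dt_t, A))
    dBv <- ad_outer_bpq(ad_mul(dt_t, v_t), ad_rows(Bm, idx))
    state <- ad_add(ad_mul(dA, state), dBv)
    ys[[t]] <- ad_add(ad_contract_state(state, ad_rows(Cm, idx)),
                      ad_mul_rowvec(v_t, ssm$D))
  }
  Y <- ad_stack_rows(ys, idx_list, S)
  gate <- ad_silu(ad_add_rowvec(ad_matmul(xn, blk$W_in_b), blk$b_in_b))
  out <- ad_add_rowvec(ad_matmul(ad_mul(Y, gate), blk$W_out), blk$b_out)
  if (!is.null(dropout_mask)) out <- ad_mulc(out, dropout_mask)
  list(node = ad_add(out, x), steps = n)
}

#' Forward pass of the full model on the autodiff tape
#'
#' @param tape An autodiff tape.
#' @param pn Parameter nodes from `params_to_nodes()`.
#' @param F_list List (per active scale) of feature arrays `(b, n_k, c, f)`.
#' @param config A [model_config()].
#' @param region_masks Logical same-region mask (`c x c`), recycled per
#'   scale, or list per scale.
#' @param graphs Optional frozen graphs (list per scale with `W_global`,
#'   `W_local`); when `NULL` graphs are rebuilt from the batch via the
#'   current transform parameters (training mode).
#' @param training Apply dropout masks (requires RNG).
#' @return List: `logits` node, `graphs` (numeric snapshot), `diagnostics`
#'   tibble (sigma and thresholds per scale), `scan_steps`.
#' @noRd
msgm_forward <- function(tape, pn, F_list, config, region_masks,
                         graphs = NULL, training = FALSE) {
  K <- length(F_list)
  if (!is.list(region_masks)) region_masks <- rep(list(region_masks), K)
  b <- dim(F_list[[1L]])[1L]
  pooled <- NULL
  graphs_out <- vector("list", K)
  diag_rows <- list()
  scan_steps <- 0L
  for (k in seq_len(K)) {
    F_k <- F_list[[k]]
    d <- dim(F_k)
    n_k <- d[2L]; c_ <- d[3L]; f <- d[4L]
    S <- b * n_k
    sc <- pn$scales[[k]]
    if (is.null(graphs)) {
      Z0 <- ad_in(tape, flatten_seq_band(batch_average(F_k)))
      Zp <- ad_add(ad_matmul(Z0, sc$trans$W), sc$trans$V)
      st <- pairwise_stats(Zp$value)
      kap_o <- offdiag_upper(st$pcc); man_o <- offdiag_upper(st$manhattan)
      euc_o <- offdiag_upper(st$euclidean)
      kappa_th <- stats::quantile(kap_o, 0.75, names = FALSE)
      d_th <- stats::quantile(man_o, 0.25, names = FALSE)
      sigma <- (mean(euc_o) + stats::sd(euc_o)) / 2
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-6
      gate <- (st$pcc >= kappa_th) & (st$manhattan <= d_th)
      E2 <- ad_pdist2(Zp)
      Wg <- ad_set_diag(ad_mulc(ad_exp(ad_scale(E2, -1 / (2 * sigma^2))),
                                gate * 1), 1)
      Wl <- if (config$ablation == "no_spatial_multiscale") Wg else
        ad_set_diag(ad_mulc(Wg, region_masks[[k]] * 1), 1)
      diag_rows[[k]] <- tibble::tibble(scale = k, sigma = sigma,
                                       kappa_threshold = kappa_th,
                                       d_threshold = d_th)
    } else {
      Wg <- ad_in(tape, unclass(graphs[[k]]$W_global))
      Wl <- if (config$ablation == "no_spatial_multiscale") Wg else
        ad_in(tape, unclass(graphs[[k]]$W_local))
    }
    graphs_out[[k]] <- list(W_global = Wg$value, W_local = Wl$value)

    Xtok <- ad_in(tape, flatten_tokens(F_k))
    H <- ad_add_rowvec(ad_matmul(Xtok, sc$base$W), sc$base$b)
    if (config$ablation == "no_fusion") {
      s_g <- H; s_l <- H
    } else {
      Lg <- ad_sym_laplacian(Wg)
      Ll <- ad_sym_laplacian(Wl)
      xA <- ad_in(tape, to_layout_A(F_k))
      proj <- function(enc_out, head) {
        ad_add_rowvec(ad_matmul(enc_out, head$W), head$b)
      }
      if (config$ablation == "single_gcn") {
        Pg <- proj(tape_cheb_encoder(xA, Lg, list(sc$enc_g$sh[[1L]]), c_, S), sc$head_g)
        Pl <- proj(tape_cheb_encoder(xA, Ll, list(sc$enc_l$sh[[1L]]), c_, S), sc$head_l)
        s_g <- ad_scale(ad_add(H, Pg), 0.5)
        s_l <- ad_scale(ad_add(H, Pl), 0.5)
      } else {
        Pg_sh <- proj(tape_cheb_encoder(xA, Lg, sc$enc_g$sh, c_, S), sc$head_g)
        Pg_dp <- proj(tape_cheb_encoder(xA, Lg, sc$enc_g$dp, c_, S), sc$head_g)
        Pl_sh <- proj(tape_cheb_encoder(xA, Ll, sc$enc_l$sh, c_, S), sc$head_l)
        Pl_dp <- proj(tape_cheb_encoder(xA, Ll, sc$enc_l$dp, c_, S), sc$head_l)
        s_g <- ad_scale(ad_add(ad_add(H, Pg_sh), Pg_dp), 1 / 3)
        s_l <- ad_scale(ad_add(ad_add(H, Pl_sh), Pl_dp), 1 / 3)
      }
    }

    run_stack <- function(s) {
      if (config$ablation == "no_mamba") return(s)
      x <- s
      for (blk in pn$blocks) {
        mask <- NULL
        if (training && config$dropout > 0) {
          keep <- matrix(stats::rbinom(S * config$h, 1L, 1 - config$dropout),
                         S, config$h) / (1 - config$dropout)
          mask <- keep
        }
        res <- tape_mamba_block(x, blk, b, n_k, mask)
        x <- res$node
        scan_steps <<- scan_steps + res$steps
      }
      ad_rmsnorm(x, pn$final_gain)
    }
    x_g <- run_stack(s_g)
    x_l <- run_stack(s_l)
    rep_g <- ad_l2norm_rows(ad_pool_tokens(x_g, b, n_k))
    rep_l <- ad_l2norm_rows(ad_pool_tokens(x_l, b, n_k))
    rep_k <- ad_scale(ad_add(rep_g, rep_l), 0.5)
    pooled <- if (is.null(pooled)) rep_k else ad_add(pooled, rep_k)
  }
  x_final <- ad_scale(pooled, 1 / K)
  logits <- ad_add_rowvec(ad_matmul(x_final, pn$clf$W), pn$clf$b)
  list(logits = logits, graphs = graphs_out,
       diagnostics = if (length(diag_rows)) dplyr::bind_rows(diag_rows) else NULL,
       scan_steps = scan_steps)
}

#' Pool and fuse temporal outputs into the final embedding (numeric path)
#'
#' Reference implementation of the pooling chain: per stream and scale, mean
#' over the token axis, L2-normalise rows, average the global and local
#' streams, then mean over scales.
#'
#' @param streams List per scale of `list(global = , local = )`, each a
#'   `(b, n_k, h)` array or `(b*n_k, h)` token matrix with `n_k` attribute.
#' @param b Batch size.
#' @return `(b, h)` matrix.
#' @export
pool_and_fuse <- function(streams, b) {
  reps <- lapply(streams, function(sk) {
    pool1 <- function(x) {
      if (length(dim(x)) == 3L) x <- tokens_of(x)
      n <- nrow(x) / b
      m <- rowsum(x, rep(seq_len(b), each = n)) / n
      m / sqrt(rowSums(m^2) + 1e-12)
    }
    (pool1(sk$global) + pool1(sk$local)) / 2
  })
  Reduce(`+`, reps) / length(reps)
}

#' Linear classifier head
#'
#' @param x_final `(b, h)` embedding.
#' @param W `h x d_out` weights; `b` length-`d_out` bias.
#' @param b Bias vector.
#' @return `(b, d_out)` logit matrix (softmax is applied in the loss or at
#'   inference).
#' @export
classify <- function(x_final, W, b) {
  sweep(x_final %*% W, 2L, b, `+`)
}
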