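# Selective state-space temporal modelling: a pre-norm residual stack of
# Mamba-style blocks. Each block expands the token width, runs a causal
# depthwise convolution + SiLU into a selective scan whose transition /
# input / output parameters (Delta, B, C) are linear functions of the
# input, gates with a SiLU branch, and projects back to width h.

silu <- function(x) x * stats::plogis(x)
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) log(expm1(y))

#' Root-mean-square normalisation
#'
#' Per token: `x / sqrt(mean(x^2) + eps) * gain`; no mean subtraction.
#'
#' @param x Token matrix `(tokens, h)` or array `(b, n, h)`.
#' @param gain Length-`h` gain vector (default all ones).
#' @param eps Stabiliser (1e-6).
#' @return Same shape as `x`.
#' @export
rmsnorm <- function(x, gain = NULL, eps = 1e-6) {
  d <- dim(x)
  three_d <- length(d) == 3L
  m <- if (three_d) tokens_of(x) else x
  h <- ncol(m)
  if (is.null(gain)) gain <- rep(1, h)
  r <- sqrt(rowMeans(m^2) + eps)
  out <- sweep(m / r, 2L, gain, `*`)
  if (three_d) aperm(array(t(out), c(d[3], d[2], d[1])), c(3L, 2L, 1L)) else out
}

#' Initialise selective-SSM parameters
#'
#' Diagonal state matrix with S4D-real-style initialisation
#' (`A[, k] = -k`), unit skip gains `D`, an input projection producing
#' `(Delta_raw, B_t, C_t)` and a low-rank `dt` bottleneck
#' (`dt_rank = ceiling(h / 16)`) whose bias places the initial step size
#' near 0.01 after softplus.
#'
#' @param d_inner Expanded channel count.
#' @param d_state State dimension per channel.
#' @param dt_rank Bottleneck width for the step-size projection.
#' @return List of parameter arrays.
#' @export
ssm_params <- function(d_inner, d_state = 16L, dt_rank = 2L) {
  list(
    A_log = matrix(log(rep(seq_len(d_state), each = d_inner)), d_inner, d_state),
    D = rep(1, d_inner),
    W_x = xavier_uniform(d_inner, dt_rank + 2L * d_state),
    W_dt = xavier_uniform(dt_rank, d_inner),
    b_dt = rep(inv_softplus(0.01), d_inner),
    d_state = as.integer(d_state), dt_rank = as.integer(dt_rank)
  )
}

#' Initialise one Mamba-style block
#'
#' @param h Token width.
#' @param expansion Width expansion factor (default 2).
#' @param d_state State dimension (default 16).
#' @param conv_kernel Causal depthwise convolution kernel size (default 4).
#' @return List of parameter arrays including nested [ssm_params()].
#' @export
mamba_block_params <- function(h, expansion = 2L, d_state = 16L, conv_kernel = 4L) {
  d_inner <- as.integer(expansion * h)
  dt_rank <- as.integer(ceiling(h / 16))
  list(
    W_in_a = xavier_uniform(h, d_inner), b_in_a = rep(0, d_inner),
    W_in_b = xavier_uniform(h, d_inner), b_in_b = rep(0, d_inner),
    conv_w = matrix(stats::runif(d_inner * conv_kernel, -1, 1) / sqrt(conv_kernel),
                    d_inner, conv_kernel),
    conv_b = rep(0, d_inner),
    ssm = ssm_params(d_inner, d_state, dt_rank),
    W_out = xavier_uniform(d_inner, h), b_out = rep(0, h),
    gain = rep(1, h),
    d_inner = d_inner, conv_kernel = as.integer(conv_kernel), h = as.integer(h)
  )
}

# (b, n, d) array <-> (b*n, d) token rows, batch-major
tokens_of <- function(x) {
  d <- dim(x)
  t(matrix(aperm(x, c(3L, 2L, 1L)), d[3]))
}
untokens <- function(m, b, n) {
  aperm(array(t(m), c(ncol(m), n, b)), c(3L, 2L, 1L))
}

#' Selective state-space scan
#'
#' Evaluates, per expanded channel with a diagonal state matrix, the strictly
#' causal recurrence
#' `x_t = exp(Delta_t * A) * x_{t-1} + Delta_t * B_t * v_t`,
#' `y_t = C_t . x_t + D * v_t`, with `x_0 = 0`. `Delta_t` (softplus of a
#' low-rank projection), `B_t` and `C_t` are generated from the input
#' sequence by the block's projections; Euler discretisation of the input
#' term, exactly as the recurrence is written.
#'
#' @param v Input sequence array `(b, n, d_inner)`.
#' @param params [ssm_params()].
#' @return Output array `(b, n, d_inner)`; attribute `scan_steps` counts the
#'   recurrence steps taken (equals `n`).
#' @export
selective_scan <- function(v, params) {
  d <- dim(v)
  b <- d[1L]; n <- d[2L]; di <- d[3L]
  ds <- params$d_state; dtr <- params$dt_rank
  X <- tokens_of(v)                               # (b*n, di)
  Z <- X %*% params$W_x
  Delta <- softplus(sweep(Z[, seq_len(dtr), drop = FALSE] %*% params$W_dt,
                          2L, params$b_dt, `+`))  # (b*n, di)
  stopifnot(all(Delta > 0))
  Bmat <- Z[, dtr + seq_len(ds), drop = FALSE]
  Cmat <- Z[, dtr + ds + seq_len(ds), drop = FALSE]
  A <- -exp(params$A_log)                         # (di, ds), negative real
  A_b <- aperm(array(A, c(di, ds, b)), c(3L, 1L, 2L))
  state <- array(0, c(b, di, ds))
  Y <- matrix(0, b * n, di)
  for (t in seq_len(n)) {
    idx <- (seq_len(b) - 1L) * n + t
    dt_t <- Delta[idx, , drop = FALSE]
    v_t <- X[idx, , drop = FALSE]
    B_e <- aperm(array(Bmat[idx, , drop = FALSE], c(b, ds, di)), c(1L, 3L, 2L))
    C_e <- aperm(array(Cmat[idx, , drop = FALSE], c(b, ds, di)), c(1L, 3L, 2L))
    dA <- exp(array(dt_t, c(b, di, ds)) * A_b)
    dBv <- array(dt_t * v_t, c(b, di, ds)) * B_e
    state <- dA * state + dBv
    y <- matrix(rowSums(matrix(state * C_e, b * di, ds)), b, di)
    Y[idx, ] <- y + sweep(v_t, 2L, params$D, `*`)
  }
  structure(untokens(Y, b, n), scan_steps = n)
}

# causal depthwise 1-D convolution over the token axis (left pad kernel-1)
causal_dwconv <- function(x, conv_w, conv_b) {
  d <- dim(x)
  out <- array(0, d)
  K <- ncol(conv_w)
  for (j in seq_len(K)) {
    lag <- j - 1L
    if (lag >= d[2L]) break                       # kernel longer than sequence
    ts <- seq_len(d[2L] - lag) + lag
    w_j <- conv_w[, K - lag]                      # newest sample gets last tap
    out[, ts, ] <- out[, ts, , drop = FALSE] +
      sweep(x[, ts - lag, , drop = FALSE], 3L, w_j, `*`)
  }
  sweep(out, 3L, conv_b, `+`)
}

#' One Mamba-style block
#'
#' `proj_out(scan(SiLU(causal_dwconv(proj_a(x)))) * SiLU(proj_b(x)))`;
#' strictly causal along the token axis.
#'
#' @param x Input array `(b, n, h)`.
#' @param params [mamba_block_params()].
#' @return Array `(b, n, h)`; attribute `scan_steps` as in
#'   [selective_scan()].
#' @export
mamba_block <- function(x, params) {
  d <- dim(x)
  X <- tokens_of(x)
  xa <- untokens(sweep(X %*% params$W_in_a, 2L, params$b_in_a, `+`), d[1L], d[2L])
  v <- silu(causal_dwconv(xa, params$conv_w, params$conv_b))
  y <- selective_scan(v, params$ssm)
  gate <- silu(sweep(X %*% params$W_in_b, 2L, params$b_in_b, `+`))
  out <- (tokens_of(y) * gate) %*% params$W_out
  out <- sweep(out, 2L, params$b_out, `+`)
  structure(untokens(out, d[1L], d[2L]), scan_steps = attr(y, "scan_steps"))
}

#' Residual pre-norm stack of Mamba-style blocks
#'
#' `x_m = Block_m(RMSNorm(x_{m-1})) + x_{m-1}` for `m = 1..M`, then a final
#' RMSNorm.
#'
#' @param x Input array `(b, n, h)`.
#' @param blocks List of [mamba_block_params()] (length `M >= 1`).
#' @param final_gain Gain for the final RMSNorm (default ones).
#' @return Array `(b, n, h)`; attribute `scan_steps` totals the recurrence
#'   steps across blocks.
#' @export
msst_stack <- function(x, blocks, final_gain = NULL) {
  steps <- 0L
  for (blk in blocks) {
    y <- mamba_block(rmsnorm(x, blk$gain), blk)
    steps <- steps + attr(y, "scan_steps")
    x <- y + x
  }
  structure(rmsnorm(x, final_gain), scan_steps = steps)
}
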