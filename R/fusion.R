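# Chebyshev graph encoders and token-embedding fusion: four encoders per
# scale (shallow/deep x global/local) share one recipe -- a polynomial
# spectral filter in the rescaled normalised Laplacian -- plus a linear base
# embedding of the raw features; the three views are fused by an unweighted
# elementwise mean per stream.

#' Rescaled normalised graph Laplacian
#'
#' `Lhat = 2 * L_sym / lambda_max - I` with
#' `L_sym = I - D^(-1/2) W D^(-1/2)`; `lambda_max` is computed exactly from
#' the symmetric eigen-decomposition (cheap at EEG channel counts), so the
#' spectrum of `Lhat` lies in `[-1, 1]`. Isolated (zero-degree) nodes get
#' zero rows/columns in `L_sym`.
#'
#' @param W Symmetric non-negative adjacency.
#' @return `Lhat` matrix with attribute `lambda_max`.
#' @export
normalized_laplacian <- function(W) {
  W <- unclass(W)
  attributes(W)[setdiff(names(attributes(W)), "dim")] <- NULL
  if (max(abs(W - t(W))) > 1e-8) stop("adjacency must be symmetric", call. = FALSE)
  c_ <- nrow(W)
  deg <- rowSums(W)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Lsym <- diag(as.numeric(deg > 0)) - (dinv %o% dinv) * W
  lam <- max(eigen(Lsym, symmetric = TRUE, only.values = TRUE)$values)
  if (lam < 1e-12) lam <- 2
  structure(2 * Lsym / lam - diag(c_), lambda_max = lam)
}

#' Initialise Chebyshev encoder parameters
#'
#' @param w_in Input feature width (7 bands for the first layer).
#' @param w_out Output width per layer.
#' @param order Chebyshev order `I` (number of polynomial terms, >= 1).
#' @param depth Number of layers (1 = shallow, 2 = deep).
#' @return List of layers; each layer has `theta` (list of `I` coefficient
#'   matrices) and `bias` (length `w_out`), ReLU activation implied.
#' @export
cheb_encoder_params <- function(w_in, w_out, order = 3L, depth = 1L) {
  stopifnot(order >= 1, depth >= 1)
  widths <- c(w_in, rep(w_out, depth))
  lapply(seq_len(depth), function(l) {
    list(theta = lapply(seq_len(order), function(i) xavier_uniform(widths[l], widths[l + 1L])),
         bias = numeric(widths[l + 1L]))
  })
}

# Chebyshev basis matrices T_0..T_{I-1} of Lhat
cheb_basis <- function(Lhat, order) {
  c_ <- nrow(Lhat)
  Ts <- vector("list", order)
  Ts[[1L]] <- diag(c_)
  if (order >= 2L) Ts[[2L]] <- Lhat
  if (order >= 3L) {
    for (i in 3:order) Ts[[i]] <- 2 * Lhat %*% Ts[[i - 1L]] - Ts[[i - 2L]]
  }
  Ts
}

# apply one channel-mixing matrix M (c x c) to axis 3 of (b, n, c, w)
graph_apply <- function(M, F) {
  d <- dim(F)
  Fc <- matrix(aperm(F, c(3L, 1L, 2L, 4L)), d[3])   # (c, b*n*w)
  out <- M %*% Fc
  aperm(array(out, c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
}

#' Chebyshev graph convolution encoder
#'
#' Each layer computes `relu(sum_i T_i(Lhat) F theta_i - bias)`; the deep
#' encoder composes two layers on the same Laplacian. With `order = 1`
#' (`T_0 = I` only) the layer degenerates to a graph-independent per-node
#' dense layer.
#'
#' @param F Input features, 4-D array `(b, n_k, c, w_in)`.
#' @param W Adjacency (one stacked slice), or a precomputed `Lhat` passed
#'   via `Lhat`.
#' @param params [cheb_encoder_params()].
#' @param Lhat Optional precomputed rescaled Laplacian.
#' @return 4-D array `(b, n_k, c, w_out)`.
#' @export
cheb_conv <- function(F, W = NULL, params, Lhat = NULL) {
  if (is.null(Lhat)) Lhat <- normalized_laplacian(W)
  x <- F
  for (layer in params) {
    order <- length(layer$theta)
    Ts <- cheb_basis(Lhat, order)
    d <- dim(x)
    w_out <- ncol(layer$theta[[1L]])
    acc <- matrix(0, d[1] * d[2] * d[3], w_out)
    for (i in seq_len(order)) {
      tf <- graph_apply(Ts[[i]], x)
      acc <- acc + matrix(tf, d[1] * d[2] * d[3], d[4]) %*% layer$theta[[i]]
    }
    acc <- sweep(acc, 2L, layer$bias, `-`)       # bias subtracted, as defined
    x <- array(pmax(acc, 0), c(d[1], d[2], d[3], w_out))
  }
  x
}

# (b, n, c, f) -> (b*n, c*f) with row s = (batch-1)*n + t, channel-major
# band-minor feature order
flatten_tokens <- function(F) {
  d <- dim(F)
  t(matrix(aperm(F, c(4L, 3L, 2L, 1L)), d[4] * d[3], d[2] * d[1]))
}

#' Linear base embedding of a feature tensor
#'
#' Flattens `(b, n_k, c, f)` to `(b * n_k, c * f)` token rows and applies a
#' trainable affine map to width `h`.
#'
#' @param F_k Feature tensor values.
#' @param W `(c * f) x h` weight matrix.
#' @param bias Length-`h` bias.
#' @return `(b * n_k) x h` matrix.
#' @export
base_embedding <- function(F_k, W, bias) {
  X <- flatten_tokens(F_k)
  sweep(X %*% W, 2L, bias, `+`)
}

#' Fuse base, shallow and deep embeddings into one token sequence
#'
#' @param H Base embedding `(b * n_k) x h`.
#' @param enc_shallow,enc_deep Projected encoder outputs of the same shape.
#' @return Elementwise mean of the three embeddings.
#' @export
fuse_tokens <- function(H, enc_shallow, enc_deep) {
  stopifnot(identical(dim(H), dim(enc_shallow)), identical(dim(H), dim(enc_deep)))
  (H + enc_shallow + enc_deep) / 3
}

# encoder output (b, n, c, w) -> token rows (b*n, c*w) for the projection head
flatten_encoder_out <- function(E) flatten_tokens(E)
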