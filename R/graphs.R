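# Bimodal spatial priors: a whole-scalp ("global") adjacency from hybrid
# Pearson-correlation + Manhattan-distance gating with a Gaussian kernel,
# and a region-masked ("local") adjacency, duplicated and stacked per scale.

#' Initialise the learnable node-feature transform for one scale
#'
#' The batch-averaged feature tensor is flattened per channel and mapped
#' through `Z %*% W + V` where `W` is `(f * n_k) x n_k` (Xavier-uniform
#' init) and `V` is `c x n_k` (zeros).
#'
#' @param c Channel count.
#' @param n_k Sub-segments at this scale.
#' @param f Band count (default 7).
#' @return List with matrices `W` and `V`.
#' @export
transform_params <- function(c, n_k, f = 7L) {
  list(W = xavier_uniform(f * n_k, n_k), V = matrix(0, c, n_k))
}

xavier_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Average a feature tensor over the batch dimension
#'
#' @param F_k 4-D array `(b, n_k, c, f)` (a feature tensor's `values`).
#' @return 3-D array `(n_k, c, f)`.
#' @export
batch_average <- function(F_k) {
  stopifnot(length(dim(F_k)) == 4, dim(F_k)[1] >= 1)
  d <- dim(F_k)
  array(colMeans(matrix(F_k, d[1])), d[-1])
}

#' Flatten an averaged tensor and apply the learnable transform
#'
#' Flattening is sequence-major, band-minor: column `(t - 1) * f + j` of the
#' flattened `c x (f * n_k)` matrix holds band `j` of sub-segment `t`. This
#' order is fixed and pinned by tests.
#'
#' @param Fbar 3-D array `(n_k, c, f)` from [batch_average()].
#' @param params [transform_params()] for this scale.
#' @return `c x n_k` node-feature matrix (row i = channel i).
#' @export
node_features <- function(Fbar, params) {
  d <- dim(Fbar)  # (n_k, c, f)
  Z <- flatten_seq_band(Fbar)
  if (!identical(dim(params$W), c(d[3] * d[1], d[1])) ||
      !identical(dim(params$V), c(d[2], d[1]))) {
    stop(sprintf("transform shape mismatch: tensor implies W (%d x %d), V (%d x %d)",
                 d[3] * d[1], d[1], d[2], d[1]), call. = FALSE)
  }
  Z %*% params$W + params$V
}

# (n_k, c, f) -> (c, f * n_k), sequence-major, band-minor
flatten_seq_band <- function(Fbar) {
  d <- dim(Fbar)
  m <- matrix(aperm(Fbar, c(3L, 1L, 2L)), d[3] * d[1], d[2])  # rows: band within seq
  t(m)
}

#' Pairwise node statistics
#'
#' Pearson correlation (with a 1e-6 guard added to the denominator so
#' constant rows yield finite values), Manhattan distance and Euclidean
#' distance between all node-feature rows.
#'
#' @param Z Node-feature matrix `c x n_k` (rows are channels).
#' @return List of `c x c` matrices `pcc`, `manhattan`, `euclidean`.
#' @export
pairwise_stats <- function(Z) {
  c_ <- nrow(Z)
  stopifnot(c_ >= 2)
  ctr <- Z - rowMeans(Z)
  sds <- sqrt(rowMeans(ctr^2))
  norm <- ctr / (sds + 1e-6)
  pcc <- (norm %*% t(norm)) / ncol(Z)
  man <- as.matrix(stats::dist(Z, method = "manhattan"))
  euc <- as.matrix(stats::dist(Z, method = "euclidean"))
  dimnames(pcc) <- dimnames(man) <- dimnames(euc) <- list(rownames(Z), rownames(Z))
  list(pcc = pcc, manhattan = man, euclidean = euc)
}

offdiag_upper <- function(M) M[upper.tri(M)]

#' Construct the global (whole-scalp) adjacency
#'
#' An edge weight is the Gaussian kernel of the Euclidean distance,
#' `exp(-d2 / (2 sigma^2))`, kept only where the Pearson correlation is at
#' or above its 75th percentile AND the Manhattan distance at or below its
#' 25th percentile (both percentiles over off-diagonal upper-triangle
#' values). `sigma` is set adaptively to `(mean + sd) / 2` of the
#' off-diagonal Euclidean distances. The diagonal is fixed to 1.
#'
#' @param Z Node-feature matrix `c x n_k`.
#' @param sigma Optional fixed bandwidth overriding the adaptive rule.
#' @return `c x c` adjacency with attributes `sigma`, `kappa_threshold`,
#'   `d_threshold` and the `stats` list for diagnostics.
#' @export
global_graph <- function(Z, sigma = NULL) {
  st <- pairwise_stats(Z)
  kap_o <- offdiag_upper(st$pcc)
  man_o <- offdiag_upper(st$manhattan)
  euc_o <- offdiag_upper(st$euclidean)
  kappa_th <- stats::quantile(kap_o, 0.75, names = FALSE)
  d_th <- stats::quantile(man_o, 0.25, names = FALSE)
  if (is.null(sigma)) sigma <- (mean(euc_o) + stats::sd(euc_o)) / 2
  if (sigma <= 0) sigma <- 1e-6
  gate <- (st$pcc >= kappa_th) & (st$manhattan <= d_th)
  W <- exp(-st$euclidean^2 / (2 * sigma^2)) * gate
  diag(W) <- 1
  dimnames(W) <- dimnames(st$pcc)
  structure(W, sigma = sigma, kappa_threshold = kappa_th, d_threshold = d_th,
            stats = st)
}

#' Region-mask a global adjacency into the local adjacency
#'
#' @param W_global Adjacency from [global_graph()].
#' @param map Region map (named integer vector) covering all channels, or a
#'   logical same-region mask from [region_mask()].
#' @param channel_labels Labels of the adjacency rows (default: dimnames).
#' @return `c x c` local adjacency: same-region entries equal the global
#'   ones, cross-region entries are 0, diagonal kept at 1.
#' @export
local_graph <- function(W_global, map, channel_labels = rownames(W_global)) {
  if (is.matrix(map) && is.logical(map)) {
    mask <- map
  } else {
    if (is.null(channel_labels)) channel_labels <- sprintf("CH%02d", seq_len(nrow(W_global)))
    mask <- region_mask(channel_labels, map)
  }
  W <- unclass(W_global) * mask
  diag(W) <- diag(unclass(W_global))
  attributes(W)[c("sigma", "kappa_threshold", "d_threshold")] <-
    attributes(W_global)[c("sigma", "kappa_threshold", "d_threshold")]
  W
}

#' Duplicate and stack an adjacency pair along a new leading dimension
#'
#' Both stacked slices equal their source at initialisation; slice 1 feeds
#' the shallow encoder and slice 2 the deep encoder, and the copies are
#' independently mutable thereafter.
#'
#' @param W_global,W_local Adjacencies of equal dimension.
#' @return List with arrays `G_global` and `G_local`, each `(2, c, c)`.
#' @export
stack_priors <- function(W_global, W_local) {
  c_ <- nrow(W_global)
  stopifnot(identical(dim(W_global), dim(W_local)))
  G_g <- array(0, c(2L, c_, c_)); G_l <- array(0, c(2L, c_, c_))
  G_g[1L, , ] <- W_global; G_g[2L, , ] <- W_global
  G_l[1L, , ] <- W_local; G_l[2L, , ] <- W_local
  list(G_global = G_g, G_local = G_l)
}

#' Build the full graph pair for one scale
#'
#' Convenience wrapper: batch-average, transform, global + local graphs,
#' stacked duplicates, with threshold diagnostics attached.
#'
#' @param F_k Feature tensor values `(b, n_k, c, f)`.
#' @param params [transform_params()].
#' @param map Region map or logical mask.
#' @param channel_labels Channel labels in tensor order.
#' @return A `graph_pair` list: `W_global`, `W_local`, `G_global`,
#'   `G_local`, `Z`, and diagnostics.
#' @export
build_graph_pair <- function(F_k, params, map, channel_labels = NULL) {
  Z <- node_features(batch_average(F_k), params)
  if (!is.null(channel_labels)) rownames(Z) <- channel_labels
  Wg <- global_graph(Z)
  Wl <- local_graph(Wg, map, channel_labels = channel_labels)
  st <- stack_priors(unclass(Wg), Wl)
  structure(list(
    W_global = Wg, W_local = Wl,
    G_global = st$G_global, G_local = st$G_local, Z = Z,
    sigma = attr(Wg, "sigma"),
    kappa_threshold = attr(Wg, "kappa_threshold"),
    d_threshold = attr(Wg, "d_threshold")
  ), class = "graph_pair")
}
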