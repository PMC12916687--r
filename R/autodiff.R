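# A minimal reverse-mode automatic differentiation tape over numeric arrays.
# Define-by-run: each operation appends a node holding its value, parent ids
# and a vector-Jacobian-product closure; ad_backward() walks the tape in
# reverse accumulating gradients. Only the operations the model needs are
# implemented; shapes are the caller's responsibility and broadcasting is
# explicit (dedicated row-vector / expanded-3D ops), never implicit.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  t
}

ad_push <- function(tape, value, parents = integer(0), vjp = NULL) {
  # force args BEFORE reading the node counter: nested op calls in argument
  # position must allocate their nodes first (R arguments are lazy)
  force(value); force(parents); force(vjp)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(parents = parents, vjp = vjp)
  tape$n <- n
  structure(list(tape = tape, id = n, value = value), class = "ad")
}

#' @noRd
ad_in <- function(tape, value) ad_push(tape, value)

nd <- function(x) if (inherits(x, "ad")) x$value else x

# ---- elementwise (shape-preserving, any dim) --------------------------------

ad_add <- function(a, b) {
  ad_push(a$tape, a$value + b$value, c(a$id, b$id),
          function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_push(a$tape, a$value - b$value, c(a$id, b$id),
          function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_push(a$tape, av * bv, c(a$id, b$id),
          function(g) list(g * bv, g * av))
}

ad_scale <- function(a, k) {
  ad_push(a$tape, a$value * k, a$id, function(g) list(g * k))
}

ad_addc <- function(a, C) ad_push(a$tape, a$value + C, a$id, function(g) list(g))

ad_mulc <- function(a, C) {
  ad_push(a$tape, a$value * C, a$id, function(g) list(g * C))
}

ad_relu <- function(a) {
  m <- a$value > 0
  ad_push(a$tape, a$value * m, a$id, function(g) list(g * m))
}

ad_silu <- function(a) {
  s <- stats::plogis(a$value)
  v <- a$value * s
  dv <- s * (1 + a$value * (1 - s))
  ad_push(a$tape, v, a$id, function(g) list(g * dv))
}

ad_softplus <- function(a) {
  v <- softplus(a$value)
  s <- stats::plogis(a$value)
  ad_push(a$tape, v, a$id, function(g) list(g * s))
}

ad_exp <- function(a) {
  v <- exp(a$value)
  ad_push(a$tape, v, a$id, function(g) list(g * v))
}

ad_negexp <- function(a) {          # -exp(x), used for the SSM state matrix
  v <- -exp(a$value)
  ad_push(a$tape, v, a$id, function(g) list(g * v))
}

# ---- matrix ops -------------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_push(a$tape, av %*% bv, c(a$id, b$id),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

ad_t <- function(a) ad_push(a$tape, t(a$value), a$id, function(g) list(t(g)))

shape_like <- function(g, v) {
  if (!is.null(dim(v))) dim(g) <- dim(v)
  g
}

ad_add_rowvec <- function(a, v) {
  vv <- v$value
  ad_push(a$tape, sweep(a$value, 2L, c(vv), `+`), c(a$id, v$id),
          function(g) list(g, shape_like(colSums(g), vv)))
}

ad_sub_rowvec <- function(a, v) {
  vv <- v$value
  ad_push(a$tape, sweep(a$value, 2L, c(vv), `-`), c(a$id, v$id),
          function(g) list(g, shape_like(-colSums(g), vv)))
}

ad_mul_rowvec <- function(a, v) {
  av <- a$value; vv <- v$value
  ad_push(a$tape, sweep(av, 2L, c(vv), `*`), c(a$id, v$id),
          function(g) list(sweep(g, 2L, c(vv), `*`), shape_like(colSums(g * av), vv)))
}

ad_rows <- function(a, idx) {
  nr <- nrow(a$value)
  ad_push(a$tape, a$value[idx, , drop = FALSE], a$id, function(g) {
    out <- matrix(0, nr, ncol(g))
    out[idx, ] <- g
    list(out)
  })
}

ad_cols <- function(a, idx) {
  ncl <- ncol(a$value)
  ad_push(a$tape, a$value[, idx, drop = FALSE], a$id, function(g) {
    out <- matrix(0, nrow(g), ncl)
    out[, idx] <- g
    list(out)
  })
}

# assemble rows from a list of nodes whose rows go to idx_list[[i]]
ad_stack_rows <- function(nodes, idx_list, total_rows) {
  ncols <- ncol(nodes[[1L]]$value)
  val <- matrix(0, total_rows, ncols)
  for (i in seq_along(nodes)) val[idx_list[[i]], ] <- nodes[[i]]$value
  ad_push(nodes[[1L]]$tape, val, vapply(nodes, function(n) n$id, integer(1)),
          function(g) lapply(idx_list, function(ix) g[ix, , drop = FALSE]))
}

# generic reshape/permute: fwd and bwd are exact inverses on arrays
ad_rearrange <- function(a, fwd, bwd) {
  force(fwd); force(bwd)   # promises must not see later loop-variable mutation
  ad_push(a$tape, fwd(a$value), a$id, function(g) list(bwd(g)))
}

# mean over each group of n consecutive rows: (b*n, h) -> (b, h)
ad_pool_tokens <- function(a, b, n) {
  grp <- rep(seq_len(b), each = n)
  ad_push(a$tape, rowsum(a$value, grp) / n, a$id,
          function(g) list(g[grp, , drop = FALSE] / n))
}

ad_l2norm_rows <- function(a, eps = 1e-12) {
  x <- a$value
  nrm <- sqrt(rowSums(x^2) + eps)
  y <- x / nrm
  ad_push(a$tape, y, a$id, function(g) {
    list(g / nrm - x * (rowSums(g * x) / nrm^3))
  })
}

ad_rmsnorm <- function(a, gain, eps = 1e-6) {
  x <- a$value; gv <- gain$value
  h <- ncol(x)
  r <- sqrt(rowMeans(x^2) + eps)
  y <- sweep(x / r, 2L, gv, `*`)
  ad_push(a$tape, y, c(a$id, gain$id), function(g) {
    gg <- sweep(g, 2L, gv, `*`)
    gx <- gg / r - x * (rowSums(gg * x) / (h * r^3))
    list(gx, colSums(g * (x / r)))
  })
}

# ---- 3-D broadcast ops for the selective scan -------------------------------

# expand u (b, p) and w (b, q) into (b, p, q) and multiply
ad_outer_bpq <- function(u, w) {
  uv <- u$value; wv <- w$value
  b <- nrow(uv); p <- ncol(uv); q <- ncol(wv)
  u_e <- array(uv, c(b, p, q))
  w_e <- aperm(array(wv, c(b, q, p)), c(1L, 3L, 2L))
  ad_push(u$tape, u_e * w_e, c(u$id, w$id), function(g) {
    list(matrix(rowSums(matrix(g * w_e, b * p, q)), b, p),
         {
           tmp <- aperm(g * u_e, c(1L, 3L, 2L))
           matrix(rowSums(matrix(tmp, b * q, p)), b, q)
         })
  })
}

# delta (b, p) times state matrix A (p, q) -> (b, p, q)
ad_outer_bA <- function(delta, A) {
  dv <- delta$value; Av <- A$value
  b <- nrow(dv); p <- ncol(dv); q <- ncol(Av)
  d_e <- array(dv, c(b, p, q))
  A_e <- aperm(array(Av, c(p, q, b)), c(3L, 1L, 2L))
  ad_push(delta$tape, d_e * A_e, c(delta$id, A$id), function(g) {
    list(matrix(rowSums(matrix(g * A_e, b * p, q)), b, p),
         matrix(colSums(matrix(g * d_e, b)), p, q))
  })
}

# sum over the state axis of x3 (b, p, q) weighted by w (b, q) -> (b, p)
ad_contract_state <- function(x3, w) {
  xv <- x3$value; wv <- w$value
  d <- dim(xv); b <- d[1L]; p <- d[2L]; q <- d[3L]
  w_e <- aperm(array(wv, c(b, q, p)), c(1L, 3L, 2L))
  val <- matrix(rowSums(matrix(xv * w_e, b * p, q)), b, p)
  ad_push(x3$tape, val, c(x3$id, w$id), function(g) {
    g_e <- array(g, c(b, p, q))
    list(g_e * w_e,
         {
           tmp <- aperm(g_e * xv, c(1L, 3L, 2L))
           matrix(rowSums(matrix(tmp, b * q, p)), b, q)
         })
  })
}

# ---- graph-specific ops -----------------------------------------------------

# pairwise squared Euclidean distances between rows of Z: (c, m) -> (c, c)
ad_pdist2 <- function(a) {
  Z <- a$value
  s <- rowSums(Z^2)
  val <- outer(s, s, `+`) - 2 * Z %*% t(Z)
  val[val < 0] <- 0
  ad_push(a$tape, val, a$id, function(g) {
    h <- g + t(g)
    list(2 * (rowSums(h) * Z - h %*% Z))
  })
}

ad_set_diag <- function(a, d) {
  v <- a$value
  diag(v) <- d
  ad_push(a$tape, v, a$id, function(g) {
    diag(g) <- 0
    list(g)
  })
}

# rescaled normalised Laplacian Lhat = 2(L_sym)/lambda_max - I, with the
# degree terms differentiated and lambda_max treated as a constant of the
# current graph
ad_sym_laplacian <- function(a) {
  W <- a$value
  c_ <- nrow(W)
  deg <- rowSums(W)
  pos <- deg > 0
  dinv <- ifelse(pos, 1 / sqrt(deg), 0)
  Dd <- dinv %o% dinv
  Lsym <- diag(as.numeric(pos)) - Dd * W
  lam <- max(eigen(Lsym, symmetric = TRUE, only.values = TRUE)$values)
  if (lam < 1e-12) lam <- 2
  val <- 2 * Lsym / lam - diag(c_)
  ad_push(a$tape, val, a$id, function(g) {
    gL <- -(2 / lam) * g                     # grad w.r.t. (Dd * W) term
    M <- gL * W
    r <- ifelse(pos, -0.5 * deg^(-1.5), 0) * (M %*% dinv + t(M) %*% dinv)
    list(gL * Dd + matrix(r, c_, c_))
  })
}

# ---- loss -------------------------------------------------------------------

# mean cross-entropy with label smoothing; labels are 1-based class indices
ad_ce_loss <- function(logits, labels, smoothing = 0) {
  L <- logits$value
  b <- nrow(L); K <- ncol(L)
  m <- apply(L, 1L, max)
  ex <- exp(L - m)
  P <- ex / rowSums(ex)
  Y <- matrix(smoothing / K, b, K)
  Y[cbind(seq_len(b), labels)] <- Y[cbind(seq_len(b), labels)] + (1 - smoothing)
  val <- -sum(Y * (L - m - log(rowSums(ex)))) / b
  ad_push(logits$tape, val, logits$id, function(g) list(g * (P - Y) / b))
}

# ---- backward ---------------------------------------------------------------

#' @noRd
ad_backward <- function(loss) {
  tape <- loss$tape
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (id in seq(loss$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$vjp)) next
    pg <- node$vjp(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      if (is.null(pg[[j]])) next
      pid <- ps[j]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
  }
  grads
}
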