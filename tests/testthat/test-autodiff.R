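# Reverse-mode tape: gradients of composite expressions agree with central
# finite differences, including nested-call argument positions (the tape
# must force lazy arguments before allocating node ids).

fd_grad <- function(f, x, i, eps = 1e-6) {
  x2 <- x; x2[i] <- x2[i] + eps
  x3 <- x; x3[i] <- x3[i] - eps
  (f(x2) - f(x3)) / (2 * eps)
}

test_that("tape gradients match finite differences on a nested expression", {
  set.seed(51)
  A0 <- matrix(rnorm(12), 4, 3)
  B0 <- matrix(rnorm(6), 3, 2)
  v0 <- rnorm(2)
  R <- matrix(rnorm(8), 4, 2)
  f <- function(A, B, v) {
    tape <- msgm:::ad_tape()
    An <- msgm:::ad_in(tape, A); Bn <- msgm:::ad_in(tape, B)
    vn <- msgm:::ad_in(tape, v)
    # deliberately nested calls in argument position
    out <- msgm:::ad_silu(msgm:::ad_add_rowvec(msgm:::ad_matmul(msgm:::ad_relu(An), Bn), vn))
    list(val = sum(out$value * R), out = out, tape = tape,
         ids = c(An$id, Bn$id, vn$id))
  }
  r <- f(A0, B0, v0)
  loss <- msgm:::ad_push(r$tape, r$val, r$out$id, function(g) list(g * R))
  g <- msgm:::ad_backward(loss)
  for (i in c(1, 5, 11)) {
    expect_equal(g[[r$ids[1]]][i], fd_grad(function(A) f(A, B0, v0)$val, A0, i),
                 tolerance = 1e-5)
  }
  expect_equal(g[[r$ids[2]]][3], fd_grad(function(B) f(A0, B, v0)$val, B0, 3),
               tolerance = 1e-5)
  expect_equal(g[[r$ids[3]]][2], fd_grad(function(v) f(A0, B0, v)$val, v0, 2),
               tolerance = 1e-5)
})

test_that("normalisation op gradients are exact", {
  set.seed(52)
  x0 <- matrix(rnorm(12), 3, 4)
  gain0 <- runif(4, 0.5, 2)
  R <- matrix(rnorm(12), 3, 4)
  f <- function(x, gain) {
    tape <- msgm:::ad_tape()
    xn <- msgm:::ad_in(tape, x); gn <- msgm:::ad_in(tape, gain)
    out <- msgm:::ad_l2norm_rows(msgm:::ad_rmsnorm(xn, gn))
    list(val = sum(out$value * R), out = out, tape = tape, ids = c(xn$id, gn$id))
  }
  r <- f(x0, gain0)
  loss <- msgm:::ad_push(r$tape, r$val, r$out$id, function(g) list(g * R))
  g <- msgm:::ad_backward(loss)
  for (i in c(2, 7)) {
    expect_equal(g[[r$ids[1]]][i], fd_grad(function(x) f(x, gain0)$val, x0, i),
                 tolerance = 1e-5)
  }
  expect_equal(g[[r$ids[2]]][1], fd_grad(function(gg) f(x0, gg)$val, gain0, 1),
               tolerance = 1e-5)
})

test_that("graph-op gradients (pairwise distance, Laplacian) are exact", {
  set.seed(53)
  Z0 <- matrix(rnorm(15), 5, 3)
  W0 <- matrix(runif(25), 5); W0 <- (W0 + t(W0)) / 2; diag(W0) <- 1
  R <- matrix(rnorm(25), 5, 5)
  f1 <- function(Z) {
    tape <- msgm:::ad_tape()
    zn <- msgm:::ad_in(tape, Z)
    out <- msgm:::ad_exp(msgm:::ad_scale(msgm:::ad_pdist2(zn), -0.1))
    list(val = sum(out$value * R), out = out, tape = tape, id = zn$id)
  }
  r <- f1(Z0)
  loss <- msgm:::ad_push(r$tape, r$val, r$out$id, function(g) list(g * R))
  g <- msgm:::ad_backward(loss)
  for (i in c(1, 8, 14)) {
    expect_equal(g[[r$id]][i], fd_grad(function(Z) f1(Z)$val, Z0, i),
                 tolerance = 1e-5)
  }
  # Laplacian: lambda_max held fixed, so compare against fd of the same map
  f2 <- function(W) {
    tape <- msgm:::ad_tape()
    wn <- msgm:::ad_in(tape, W)
    out <- msgm:::ad_sym_laplacian(wn)
    lamfix <- attr(normalized_laplacian(W0), "lambda_max")
    deg <- rowSums(W); dinv <- 1 / sqrt(deg)
    Lsym <- diag(5) - (dinv %o% dinv) * W
    list(val = sum(out$value * R), out = out, tape = tape, id = wn$id,
         fixed = sum((2 * Lsym / lamfix - diag(5)) * R))
  }
  r2 <- f2(W0)
  loss2 <- msgm:::ad_push(r2$tape, r2$val, r2$out$id, function(g) list(g * R))
  g2 <- msgm:::ad_backward(loss2)
  for (i in c(2, 13)) {
    expect_equal(g2[[r2$id]][i], fd_grad(function(W) f2(W)$fixed, W0, i),
                 tolerance = 1e-4)
  }
})

test_that("cross-entropy loss gradient is softmax minus smoothed target", {
  set.seed(54)
  L0 <- matrix(rnorm(8), 4, 2)
  y <- c(1L, 2L, 2L, 1L)
  f <- function(L) {
    tape <- msgm:::ad_tape()
    ln <- msgm:::ad_in(tape, L)
    loss <- msgm:::ad_ce_loss(ln, y, 0.1)
    list(val = loss$value, loss = loss, tape = tape, id = ln$id)
  }
  r <- f(L0)
  g <- msgm:::ad_backward(r$loss)
  for (i in c(1, 6)) {
    expect_equal(g[[r$id]][i], fd_grad(function(L) f(L)$val, L0, i),
                 tolerance = 1e-6)
  }
})

test_that("full-model gradients match finite differences for smooth parameters", {
  set.seed(55)
  cfgm <- model_config(h = 8, w_out = 4, cheb_order = 2, d_state = 4, dropout = 0)
  b <- 4; nks <- 3L; c_ <- 4L
  params <- init_msgm_params(cfgm, nks, c_)
  F_list <- list(array(runif(b * 3 * c_ * 7), c(b, 3, c_, 7)))
  mask <- matrix(rep(c(TRUE, FALSE, FALSE, TRUE), 4), 4, 4)
  mask <- mask | t(mask); diag(mask) <- TRUE
  y <- c(1L, 2L, 1L, 2L)
  run <- function(p) {
    tape <- msgm:::ad_tape(); reg <- new.env(parent = emptyenv())
    pn <- msgm:::params_to_nodes(tape, p, reg)
    fw <- msgm:::msgm_forward(tape, pn, F_list, cfgm, mask, training = FALSE)
    list(loss = msgm:::ad_ce_loss(fw$logits, y, 0.1), reg = reg)
  }
  r <- run(params)
  g <- msgm:::ad_backward(r$loss)
  flat <- flatten_params(params)
  for (key in c("clf.W", "blocks.1.W_in_a", "blocks.1.conv_w",
                "scales.1.base.W", "scales.1.head_l.W",
                "scales.1.enc_g.dp.2.theta.1", "final_gain")) {
    i <- 2L
    up <- function(delta) {
      fl <- flat; fl[[key]][i] <- fl[[key]][i] + delta
      run(msgm:::unflatten_params(params, fl))$loss$value
    }
    gnum <- (up(1e-6) - up(-1e-6)) / 2e-6
    expect_equal(g[[r$reg[[key]]]][i], gnum, tolerance = 1e-4,
                 label = paste("analytic gradient for", key))
  }
})
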