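# Bimodal spatial priors: transform, pairwise statistics, gated Gaussian
# global graph, region-masked local graph, stacked duplicates.

test_that("batch averaging is an arithmetic mean over axis 1", {
  set.seed(21)
  F1 <- array(runif(5 * 4 * 3 * 7), c(5, 4, 3, 7))
  m <- batch_average(F1)
  # independent summation oracle
  acc <- array(0, dim(F1)[-1])
  for (i in 1:5) acc <- acc + F1[i, , , ]
  expect_equal(m, acc / 5)
  # idempotent on identical items; antisymmetric pair cancels
  Fsame <- array(rep(F1[1, , , ], each = 2), c(2, 4, 3, 7))
  expect_equal(batch_average(Fsame), F1[1, , , ])
  Fpm <- array(0, c(2, 2, 2, 7)); Fpm[1, , , ] <- 1; Fpm[2, , , ] <- -1
  expect_true(all(batch_average(Fpm) == 0))
})

test_that("node features apply the documented flatten order and affine map", {
  set.seed(22)
  n_k <- 3; c_ <- 4; f <- 7
  Fbar <- array(runif(n_k * c_ * f), c(n_k, c_, f))
  tp <- transform_params(c_, n_k)
  # zero weights -> bias; one-hot columns select flattened entries
  Z0 <- node_features(Fbar, list(W = tp$W * 0, V = matrix(5, c_, n_k)))
  expect_true(all(Z0 == 5))
  Wsel <- matrix(0, f * n_k, n_k)
  Wsel[cbind(c(1, f + 2, 2 * f + 3), 1:3)] <- 1   # (t=1,b=1), (t=2,b=2), (t=3,b=3)
  Zsel <- node_features(Fbar, list(W = Wsel, V = matrix(0, c_, n_k)))
  expect_equal(Zsel[, 1], Fbar[1, , 1])
  expect_equal(Zsel[, 2], Fbar[2, , 2])
  expect_equal(Zsel[, 3], Fbar[3, , 3])
  # random case vs naive triple-loop matmul
  Z <- node_features(Fbar, tp)
  flat <- matrix(0, c_, f * n_k)
  for (t in seq_len(n_k)) for (b in seq_len(f))
    flat[, (t - 1) * f + b] <- Fbar[t, , b]
  expect_equal(Z, naive_matmul(flat, tp$W) + tp$V)
  expect_error(node_features(Fbar, transform_params(c_, n_k + 1)), "mismatch")
})

test_that("pairwise statistics match the guarded textbook formulas", {
  set.seed(23)
  Z <- matrix(rnorm(6 * 4), 6, 4)
  st <- pairwise_stats(Z)
  expect_equal(st$pcc, naive_pcc(Z), tolerance = 1e-12, ignore_attr = TRUE)
  man <- matrix(0, 6, 6); euc <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    man[i, j] <- sum(abs(Z[i, ] - Z[j, ]))
    euc[i, j] <- sqrt(sum((Z[i, ] - Z[j, ])^2))
  }
  expect_equal(unname(st$manhattan), man)
  expect_equal(unname(st$euclidean), euc)
  expect_symmetric(st$pcc); expect_symmetric(st$manhattan)
  # identical nodes and exact anti-correlation (guard keeps values finite)
  Z2 <- rbind(c(1, 2, 3, 2), c(1, 2, 3, 2), -c(1, 2, 3, 2) + 2)
  st2 <- pairwise_stats(Z2)
  expect_equal(st2$pcc[1, 2], 1, tolerance = 1e-3)
  expect_equal(st2$pcc[1, 3], -1, tolerance = 1e-3)
  expect_equal(st2$manhattan[1, 2], 0)
  # constant rows stay finite thanks to the 1e-6 guard
  st3 <- pairwise_stats(rbind(rep(2, 4), rnorm(4)))
  expect_true(all(is.finite(st3$pcc)))
})

test_that("global graph gates by percentiles and matches the kernel oracle", {
  set.seed(24)
  Z <- matrix(rnorm(16 * 6), 16, 6)
  W <- global_graph(Z)
  expect_symmetric(W)
  expect_true(all(diag(W) == 1))
  expect_true(all(W >= 0 & W <= 1))
  # brute-force oracle: percentiles and kernel recomputed from scratch
  st <- pairwise_stats(Z)
  kap <- st$pcc[upper.tri(st$pcc)]
  man <- st$manhattan[upper.tri(st$manhattan)]
  euc <- st$euclidean[upper.tri(st$euclidean)]
  k_th <- quantile(kap, 0.75, names = FALSE)
  d_th <- quantile(man, 0.25, names = FALSE)
  sigma <- (mean(euc) + sd(euc)) / 2
  expect_equal(attr(W, "sigma"), sigma)
  expect_equal(attr(W, "kappa_threshold"), k_th)
  nz <- 0
  for (i in 1:15) for (j in (i + 1):16) {
    if (st$pcc[i, j] >= k_th && st$manhattan[i, j] <= d_th) {
      expect_equal(W[i, j], exp(-st$euclidean[i, j]^2 / (2 * sigma^2)))
      nz <- nz + 1
    } else {
      expect_identical(unname(W[i, j]), 0)
    }
  }
  # joint gate support is at most the 25% passing the distance gate
  expect_lte(nz / choose(16, 2), 0.25 + 1 / choose(16, 2))
  # a pair with correlation below threshold is zero regardless of distance
  expect_true(all(W[upper.tri(W)][kap < k_th] == 0))
})

test_that("two identical channels get unit weight when they pass the gates", {
  Z <- rbind(c(1, 2, 3), c(1, 2, 3), c(8, -1, 4), c(0, 5, -2), c(3, 3, 3))
  W <- global_graph(Z)
  expect_equal(unname(W[1, 2]), 1)  # exp(0) through both gates
})

test_that("increasing sigma never decreases a surviving weight", {
  set.seed(25)
  Z <- matrix(rnorm(10 * 5), 10, 5)
  W1 <- global_graph(Z)
  W2 <- global_graph(Z, sigma = 2 * attr(W1, "sigma"))
  expect_true(all(W2 - W1 >= -1e-12))
})

test_that("local graph masks to regions and keeps support within global", {
  set.seed(26)
  Z <- matrix(rnorm(8 * 5), 8, 5)
  rownames(Z) <- sprintf("CH%02d", 1:8)
  Wg <- global_graph(Z)
  map <- setNames(c(1, 1, 1, 2, 2, 2, 3, 3), rownames(Z))
  Wl <- local_graph(Wg, map)
  expect_symmetric(Wl)
  for (i in 1:7) for (j in (i + 1):8) {
    if (map[i] == map[j]) expect_equal(Wl[i, j], unclass(Wg)[i, j])
    else expect_identical(unname(Wl[i, j]), 0)
  }
  # all in one region -> identical; all separate -> diagonal only
  expect_equal(unname(local_graph(Wg, setNames(rep(1, 8), rownames(Z)))),
               unname(unclass(Wg)))
  Wsep <- local_graph(Wg, setNames(1:8, rownames(Z)))
  expect_true(all(Wsep[upper.tri(Wsep)] == 0))
  expect_true(all(diag(Wsep) == 1))
  expect_error(local_graph(Wg, setNames(1:7, rownames(Z)[1:7])), "without a region")
})

test_that("stacked priors duplicate the source and stay independently mutable", {
  W <- matrix(runif(16), 4, 4); W <- (W + t(W)) / 2
  Wl <- W * outer(rep(1:2, each = 2), rep(1:2, each = 2), "==")
  st <- stack_priors(W, Wl)
  expect_equal(dim(st$G_global), c(2L, 4L, 4L))
  expect_equal(st$G_global[1, , ], W)
  expect_equal(st$G_global[2, , ], W)
  expect_equal(st$G_local[1, , ], Wl)
  g2 <- st$G_global
  g2[2, , ] <- 0
  expect_equal(st$G_global[1, , ], W)  # copy semantics: slice 1 untouched
})

test_that("graph construction is deterministic given tensor and transform", {
  feats <- tiny_features()
  F1 <- feats$tensors[[1]]$values
  set.seed(27)
  tp <- transform_params(dim(F1)[3], dim(F1)[2])
  map <- tiny_sim()$region_map
  g1 <- build_graph_pair(F1, tp, map, channel_labels = names(map))
  g2 <- build_graph_pair(F1, tp, map, channel_labels = names(map))
  expect_identical(unclass(g1$W_global), unclass(g2$W_global))
  expect_identical(g1$W_local, g2$W_local)
  # local support within global support; stacked slices equal sources
  expect_true(all((g1$W_local != 0) <= (unclass(g1$W_global) != 0)))
  expect_equal(g1$G_local[1, , ], g1$W_local, ignore_attr = TRUE)
  td <- tidy(g1)
  expect_true(all(c("ch_i", "ch_j", "weight", "stream") %in% names(td)))
})
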