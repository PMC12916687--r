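# Subject-independent protocol, metrics, statistics, ablations.

test_that("LOSO folds cover every subject once with an 8:2 subject split", {
  folds <- make_folds(1:15, "loso", seed = 3)
  expect_equal(nrow(folds), 15L)
  tested <- sort(unlist(folds$test))
  expect_equal(tested, 1:15)
  for (i in 1:15) {
    expect_length(folds$train[[i]], 11L)  # round(0.8 * 14)
    expect_length(folds$val[[i]], 3L)     # round(0.2 * 14)
    expect_length(intersect(folds$test[[i]],
                            c(folds$train[[i]], folds$val[[i]])), 0L)
    expect_setequal(c(folds$test[[i]], folds$train[[i]], folds$val[[i]]), 1:15)
  }
})

test_that("leave-n-out folds form ceiling(S/n) groups, each subject tested once", {
  folds <- make_folds(1:80, "leave_n_out", n = 8, seed = 5)
  expect_equal(nrow(folds), 10L)
  expect_equal(sort(unlist(folds$test)), 1:80)
  expect_true(all(lengths(folds$test) == 8L))
  for (i in seq_len(10)) {
    expect_length(folds$val[[i]], 7L)     # round(0.1 * 72)
    expect_length(folds$train[[i]], 65L)
  }
  expect_error(make_folds(1:5, "leave_n_out", n = 5), "n <")
  expect_error(make_folds(1), "at least 2")
})

test_that("valence binarisation thresholds at 3.0 and excludes the boundary", {
  expect_identical(binarize_valence(c(4.2, 1.0)), c("high", "low"))
  expect_warning(out <- binarize_valence(c(2, 3, 5)), "3.0 threshold")
  expect_identical(out, c("low", NA, "high"))
  expect_error(binarize_valence("x"), "numeric")
})

test_that("Welch statistics match published rows and a reference implementation", {
  # identical groups: no effect
  st0 <- welch_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(st0$t, 0); expect_equal(st0$d, 0); expect_equal(st0$p, 1)
  # from raw vectors: agree with stats::t.test (Welch) to near machine precision
  set.seed(61)
  a <- rnorm(12, 1); b <- rnorm(9)
  st <- welch_stats(a, b)
  tt <- t.test(a, b)
  expect_equal(st$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(st$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(st$p, tt$p.value, tolerance = 1e-10)
  expect_equal(st$d, (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2),
               tolerance = 1e-10)
  # degenerate: zero variance with nonzero difference flags infinite t
  expect_warning(sti <- welch_stats(c(2, 2), c(1, 1)), "infinite")
  expect_true(is.infinite(sti$t))
})

test_that("pooling chain matches a hand-composed oracle", {
  set.seed(62)
  b <- 3; h <- 5
  mk <- function(n) array(rnorm(b * n * h), c(b, n, h))
  s1 <- list(global = mk(4), local = mk(4))
  s2 <- list(global = mk(2), local = mk(2))
  out <- pool_and_fuse(list(s1, s2), b)
  oracle_one <- function(x) {
    m <- apply(x, c(1, 3), mean)
    m / sqrt(rowSums(m^2) + 1e-12)
  }
  oracle <- ((oracle_one(s1$global) + oracle_one(s1$local)) / 2 +
             (oracle_one(s2$global) + oracle_one(s2$local)) / 2) / 2
  expect_equal(out, oracle, ignore_attr = TRUE)
  # single scale with identical streams: unit-normalised stream mean
  v <- mk(3)
  o1 <- pool_and_fuse(list(list(global = v, local = v)), b)
  expect_equal(unname(sqrt(rowSums(o1^2))), rep(1, b), tolerance = 1e-6)
})

test_that("the linear classifier is an affine map with softmax in the loss only", {
  set.seed(63)
  X <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(6), 3, 2); bb <- rnorm(2)
  L <- classify(X, W, bb)
  expect_equal(L, naive_matmul(X, W) + matrix(bb, 4, 2, byrow = TRUE))
  L0 <- classify(X, W * 0, bb)
  expect_true(all(t(L0) == bb))
  P <- exp(L) / rowSums(exp(L))
  expect_equal(rowSums(P), rep(1, 4))
})

test_that("ablation switches are exclusive and shrink capacity as expected", {
  cfg <- model_config(h = 8, w_out = 4, cheb_order = 2, d_state = 4)
  expect_error(ablate(ablate(cfg, "no_mamba"), "no_fusion"), "conflicting")
  full <- count_parameters(init_msgm_params(cfg, c(5L, 3L), 6L))
  single <- count_parameters(init_msgm_params(ablate(cfg, "single_gcn"), c(5L, 3L), 6L))
  nofuse <- count_parameters(init_msgm_params(ablate(cfg, "no_fusion"), c(5L, 3L), 6L))
  nomamba <- count_parameters(init_msgm_params(ablate(cfg, "no_mamba"), c(5L, 3L), 6L))
  expect_lt(single, full)
  expect_lt(nofuse, full)
  expect_lt(nomamba, full)
})

test_that("tape and composed numeric forward passes agree exactly", {
  set.seed(64)
  cfgm <- model_config(h = 8, w_out = 4, cheb_order = 2, d_state = 4, dropout = 0)
  b <- 4; nks <- c(4L, 2L); c_ <- 6L
  params <- init_msgm_params(cfgm, nks, c_)
  F_list <- lapply(nks, function(n) array(runif(b * n * c_ * 7), c(b, n, c_, 7)))
  map <- setNames(rep(1:2, each = 3), sprintf("CH%02d", 1:6))
  mask <- region_mask(names(map), map)
  tape <- msgm:::ad_tape(); reg <- new.env(parent = emptyenv())
  pn <- msgm:::params_to_nodes(tape, params, reg)
  fw <- msgm:::msgm_forward(tape, pn, F_list, cfgm, mask, training = FALSE)
  # independent composition from the exported numeric operations
  streams <- lapply(seq_along(nks), function(k) {
    Fb <- F_list[[k]]; sc <- params$scales[[k]]
    Z <- node_features(batch_average(Fb), sc$trans)
    Wg <- global_graph(Z)
    Wl <- local_graph(Wg, mask)
    H <- base_embedding(Fb, sc$base$W, sc$base$b)
    enc <- function(encp, W) {
      E <- cheb_conv(Fb, W, encp)
      d <- dim(E)
      t(matrix(aperm(E, c(4, 3, 2, 1)), d[4] * d[3], d[2] * d[1]))
    }
    proj <- function(X, head) sweep(X %*% head$W, 2, head$b, `+`)
    sg <- fuse_tokens(H, proj(enc(sc$enc_g$sh, unclass(Wg)), sc$head_g),
                      proj(enc(sc$enc_g$dp, unclass(Wg)), sc$head_g))
    sl <- fuse_tokens(H, proj(enc(sc$enc_l$sh, Wl), sc$head_l),
                      proj(enc(sc$enc_l$dp, Wl), sc$head_l))
    run <- function(s) {
      x3 <- aperm(array(t(s), c(ncol(s), nks[k], b)), c(3, 2, 1))
      msst_stack(x3, params$blocks, params$final_gain)
    }
    list(global = run(sg), local = run(sl))
  })
  logits <- classify(pool_and_fuse(streams, b), params$clf$W, params$clf$b)
  expect_equal(fw$logits$value, logits, tolerance = 1e-12)
})

test_that("training is deterministic and free of subject leakage", {
  cfg <- tiny_sim(effect_size = 1.5)
  ds <- generate_dataset(cfg)
  feats <- prepare_features(ds, segmentation_config(scales = list(c(4, 2))))
  mcfg <- model_config(h = 8, w_out = 4, cheb_order = 2, d_state = 4)
  tc <- train_config(batch_size = 8, max_epochs = 2, patience = 2, seed = 7)
  folds <- make_folds(unique(feats$meta$subject_id), "loso", seed = 7)
  f1 <- train_msgm(feats, folds[1, ], mcfg, tc, region_map = cfg$region_map)
  f2 <- train_msgm(feats, folds[1, ], mcfg, tc, region_map = cfg$region_map)
  expect_identical(f1$folds$accuracy, f2$folds$accuracy)
  expect_identical(f1$folds$f1, f2$folds$f1)
  # leakage guard: test subject segments never appear in train or val sets
  test_sub <- folds$test[[1]]
  expect_false(test_sub %in% c(folds$train[[1]], folds$val[[1]]))
  # report invariants
  expect_true(all(f1$folds$accuracy >= 0 & f1$folds$accuracy <= 100))
  expect_true(all(f1$folds$f1 >= 0 & f1$folds$f1 <= 100))
  g <- glance(f1)
  expect_equal(g$n_folds, 1L)
  expect_s3_class(tidy(f1), "tbl_df")
})

test_that("a no_mamba forward pass performs zero scan steps", {
  set.seed(65)
  cfgm <- ablate(model_config(h = 8, w_out = 4, cheb_order = 2, d_state = 4), "no_mamba")
  params <- init_msgm_params(cfgm, 3L, 4L)
  F_list <- list(array(runif(2 * 3 * 4 * 7), c(2, 3, 4, 7)))
  tape <- msgm:::ad_tape(); reg <- new.env(parent = emptyenv())
  pn <- msgm:::params_to_nodes(tape, params, reg)
  fw <- msgm:::msgm_forward(tape, pn, F_list, cfgm, matrix(TRUE, 4, 4),
                            training = FALSE)
  expect_identical(fw$scan_steps, 0L)
  # full model on the same input does scan
  cfg2 <- model_config(h = 8, w_out = 4, cheb_order = 2, d_state = 4)
  p2 <- init_msgm_params(cfg2, 3L, 4L)
  tape2 <- msgm:::ad_tape(); reg2 <- new.env(parent = emptyenv())
  pn2 <- msgm:::params_to_nodes(tape2, p2, reg2)
  fw2 <- msgm:::msgm_forward(tape2, pn2, F_list, cfg2, matrix(TRUE, 4, 4),
                             training = FALSE)
  expect_gt(fw2$scan_steps, 0L)
})
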