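test_that("KNN graphs order by distance, include self, and pad short clouds", {
  pts <- cbind(c(0, 1, 3), 0, 0)
  g <- build_knn_graph(pts, 2)
  # brute-force: middle point's two nearest are itself and x = 0
  expect_setequal(g$idx[2, ], c(2L, 1L))
  expect_equal(g$idx[1, ], c(1L, 2L))
  g1 <- build_knn_graph(pts, 1)
  expect_equal(g1$idx[, 1], 1:3)       # K = 1: self is nearest
  g5 <- build_knn_graph(pts[1:2, , drop = FALSE], 5)
  expect_equal(ncol(g5$idx), 5L)
  expect_equal(g5$idx[1, 3:5], rep(1L, 3))  # padded with self
  expect_error(build_knn_graph(pts[0, , drop = FALSE], 2), "empty")
})

test_that("attention weights are a per-query softmax; degenerate cases are exact", {
  set.seed(11)
  coords <- matrix(rnorm(24), 8, 3)
  params <- mrdca_init(4, 4, mrdca_config(k = 4, branch_channels = 4))$branches[[1]]
  f <- matrix(rnorm(32), 8, 4)
  g <- build_knn_graph(coords, 4)
  r <- dca_attention(f, g, coords, params, return_weights = TRUE)
  expect_lt(max(abs(rowSums(r$weights) - 1)), 1e-6)
  # zero-initialized MLPs + identical features -> uniform weights exactly
  zero_params(params)
  fid <- matrix(1, 8, 4)
  ru <- dca_attention(fid, g, coords, params, return_weights = TRUE)
  expect_equal(ru$weights, matrix(1 / 4, 8, 4))
  # K = 1: output equals own value vector
  set.seed(12)
  params2 <- mrdca_init(4, 4, mrdca_config(k = 4, branch_channels = 4))$branches[[1]]
  g1 <- build_knn_graph(coords, 1)
  out1 <- dca_attention(f, g1, coords, params2)
  vv <- f %*% ns$ag_value(params2$Wv$W)
  expect_equal(out1, vv, tolerance = 1e-10)
  expect_error(dca_attention(matrix(NaN, 8, 4), g, coords, params2), "finite")
})

test_that("dual-coordinate attention matches the dense step-by-step oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    coords <- matrix(rnorm(24), 8, 3)
    f <- matrix(rnorm(8 * 6), 8, 6)
    params <- mrdca_init(6, 6, mrdca_config(k = 4, branch_channels = 6))$branches[[1]]
    params$alpha$value[] <- 0.7    # exercise the pooled term too
    g <- build_knn_graph(coords, 4)
    got <- dca_attention(f, g, coords, params)
    want <- oracle_dca(f, g, coords, params)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("normalized absolute coordinates handle a degenerate axis", {
  coords <- cbind(rnorm(10), rnorm(10), 0)   # constant z
  pn <- ns$.norm_coords(coords)
  expect_true(all(is.finite(pn)))
  expect_true(all(pn[, 3] == 0))
  expect_true(all(pn >= 0 & pn <= 1))
})

test_that("the full module is permutation-equivariant", {
  set.seed(13)
  N <- 64
  coords <- matrix(rnorm(N * 3), N, 3)
  f <- matrix(rnorm(N * 8), N, 8)
  params <- mrdca_init(8, 8, mrdca_config(k = c(4, 8, 12), branch_channels = 4))
  out <- mrdca_forward(f, coords, params)
  perm <- sample(N)
  outp <- mrdca_forward(f[perm, ], coords[perm, ], params)
  expect_lt(max(abs(outp - out[perm, ])), 1e-5)
})

test_that("with psi_abs silenced the module is translation-invariant", {
  set.seed(14)
  N <- 32
  coords <- matrix(rnorm(N * 3), N, 3)
  f <- matrix(rnorm(N * 8), N, 8)
  params <- mrdca_init(8, 8, mrdca_config(k = c(4, 8), branch_channels = 4))
  for (b in params$branches) zero_params(b$psi_abs)
  out <- mrdca_forward(f, coords, params)
  out_shift <- mrdca_forward(f, sweep(coords, 2, c(5, -3, 11), `+`), params)
  expect_lt(max(abs(out - out_shift)), 1e-8)
  # min-max normalization also makes the active psi_abs shift-stable, but a
  # non-uniform stretch of the cloud does change its term
  set.seed(15)
  params2 <- mrdca_init(8, 8, mrdca_config(k = c(4, 8), branch_channels = 4))
  o1 <- mrdca_forward(f, coords, params2)
  stretched <- coords
  stretched[, 3] <- stretched[, 3]^3
  o2 <- mrdca_forward(f, stretched, params2)
  expect_gt(max(abs(o1 - o2)), 1e-6)
})

test_that("fusion modes produce the configured widths and input width is checked", {
  set.seed(16)
  coords <- matrix(rnorm(30), 10, 3)
  f <- matrix(rnorm(10 * 12), 10, 12)
  pc <- mrdca_init(12, 24, mrdca_config(k = c(2, 3, 4), branch_channels = 5,
                                        fusion = "concat"))
  expect_equal(dim(mrdca_forward(f, coords, pc)), c(10L, 24L))
  ps <- mrdca_init(12, 7, mrdca_config(k = c(2, 3, 4), branch_channels = 5,
                                       fusion = "sum"))
  expect_equal(dim(mrdca_forward(f, coords, ps)), c(10L, 7L))
  expect_error(mrdca_forward(f[, 1:5], coords, pc), "width")
})

test_that("gradients reach the gate, the positional MLPs and the projections", {
  set.seed(17)
  N <- 20
  coords <- matrix(rnorm(N * 3), N, 3)
  f <- matrix(rnorm(N * 6), N, 6)
  params <- mrdca_init(6, 6, mrdca_config(k = c(3, 4, 5), branch_channels = 4))
  for (b in params$branches) b$alpha$value[] <- 0.5  # open the pooled pathway
  ns$ag_begin()
  loss <- ns$ag_sum(mrdca_forward(ns$ag_const(f), coords, params))
  # make the input a tracked node so the whole graph is on the tape
  ns$ag_zero_grads(ns$nn_params(params))
  ns$ag_begin()
  loss <- ns$ag_sum(mrdca_forward(ns$ag_param(f), coords, params))
  ns$ag_backward(loss)
  b <- params$branches[[1]]
  for (p in list(b$alpha, b$psi_rel$layers[[1]]$W, b$psi_abs$layers[[1]]$W,
                 b$psi_pool$layers[[1]]$W, b$Wq$W, b$Wk$W, b$Wv$W)) {
    expect_false(is.null(p$grad))
    expect_true(all(is.finite(p$grad)))
    expect_gt(max(abs(p$grad)), 0)
  }
})
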