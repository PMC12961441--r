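test_that("point entropy matches its closed forms and bounds", {
  expect_equal(point_entropy(matrix(1 / 3, 1, 3)), log(3), tolerance = 1e-12)
  expect_equal(point_entropy(matrix(c(1, 0, 0), 1, 3)), 0)
  expect_equal(point_entropy(matrix(c(0.5, 0.5, 0), 1, 3)), log(2),
               tolerance = 1e-12)
  expect_error(point_entropy(matrix(c(-0.1, 1.1, 0), 1, 3)), "non-negative")
  expect_error(point_entropy(matrix(c(0.2, 0.2, 0.2), 1, 3)), "sum to 1")
  set.seed(21)
  for (r in 1:20) {
    p <- matrix(rexp(4 * 5), 4, 5)
    p <- p / rowSums(p)
    u <- point_entropy(p)
    expect_true(all(u >= 0 & u <= log(5) + 1e-12))
  }
})

test_that("uncertainty gate is the sigmoid of entropy, increasing", {
  expect_equal(uncertainty_gate(0), 0.5)
  expect_equal(uncertainty_gate(log(3)), 0.75, tolerance = 1e-12)
  u <- sort(runif(50, 0, 2))
  expect_true(all(diff(uncertainty_gate(u)) > 0))
  expect_error(uncertainty_gate(-0.1), "non-negative")
})

test_that("kernel generation is a pure function matching the dense oracle", {
  set.seed(22)
  N <- 10; K <- 4; C <- 6
  coords <- matrix(rnorm(N * 3), N, 3)
  params <- pg_init(C, 3, pg_config(k = K, hidden = 8))
  g <- build_knn_graph(coords, K)
  geo <- ns$.pg_geometry(g)
  f <- matrix(rnorm(N * C), N, C)
  H <- generate_kernels(f, g, geo, params)
  expect_lt(max(abs(H - oracle_kernels(f, g, geo, params))), 1e-5)
  # zero-initialized M_k: every kernel row equals the bias pattern
  zk <- pg_init(C, 3, pg_config(k = K, hidden = 8))
  zk$Mk$W$value[] <- 0
  zk$Mk$b$value[] <- c(1, 0, 0, 0)
  Hz <- generate_kernels(f, g, geo, zk)
  expect_equal(Hz, matrix(rep(c(1, 0, 0, 0), each = N), N, K))
  # duplicated point (same coords and features) gets an identical kernel row
  f2 <- rbind(f, f[1, ]); coords2 <- rbind(coords, coords[1, ])
  g2 <- build_knn_graph(coords2, K)
  geo2 <- ns$.pg_geometry(g2)
  H2 <- generate_kernels(f2, g2, geo2, params)
  expect_equal(H2[1, ], H2[N + 1, ], tolerance = 1e-9)
  expect_error(generate_kernels(f, g, geo[, 1:3], params), "slots")
})

test_that("refinement is the gated kernel-weighted neighbor sum", {
  set.seed(23)
  N <- 6; K <- 3; C <- 4
  coords <- matrix(rnorm(N * 3), N, 3)
  g <- build_knn_graph(coords, K)
  f <- matrix(rnorm(N * C), N, C)
  H <- matrix(rnorm(N * K), N, K)
  gate <- runif(N)
  out <- refine_features(f, H, gate, g)
  # brute-force double loop over i and neighbor slots
  want <- matrix(0, N, C)
  for (i in 1:N) for (jj in 1:K) {
    want[i, ] <- want[i, ] + H[i, jj] * f[g$idx[i, jj], ]
  }
  want <- want * gate
  expect_lt(max(abs(out - want)), 1e-6)
  # gate annihilation and identity kernels
  expect_equal(refine_features(f, H, rep(0, N), g), matrix(0, N, C))
  Hid <- matrix(0, N, K); Hid[, 1] <- 1     # slot 1 is always self
  expect_equal(refine_features(f, Hid, rep(1, N), g), f, tolerance = 1e-12)
  expect_error(refine_features(f, H * NA, gate, g), "finite")
  # refinement magnitude scales linearly with the gate, kernels fixed
  o1 <- refine_features(f, H, rep(0.3, N), g)
  o2 <- refine_features(f, H, rep(0.6, N), g)
  expect_equal(o2, 2 * o1, tolerance = 1e-12)
})

test_that("the composite forward is permutation-equivariant and honors residual", {
  set.seed(24)
  N <- 40; C <- 6
  coords <- matrix(rnorm(N * 3), N, 3)
  f <- matrix(rnorm(N * C), N, C)
  params <- pg_init(C, 3, pg_config(k = 5, hidden = 8))
  out <- pg_invfr_forward(f, coords, params)$features
  perm <- sample(N)
  outp <- pg_invfr_forward(f[perm, ], coords[perm, ], params)$features
  expect_lt(max(abs(outp - out[perm, ])), 1e-5)
  # gate forced to 1 with identity kernels: residual doubles, plain returns input
  idp <- pg_init(C, 3, pg_config(k = 5, hidden = 8))
  idp$Mc$W$value[] <- 0; idp$Mc$b$value[] <- 0
  idp$Mk$W$value[] <- 0; idp$Mk$b$value[] <- c(1, rep(0, 4))
  o_res <- pg_invfr_forward(f, coords, idp, gate = rep(1, N))$features
  expect_equal(o_res, 2 * f, tolerance = 1e-10)
  idp$config$residual <- FALSE
  o_plain <- pg_invfr_forward(f, coords, idp, gate = rep(1, N))$features
  expect_equal(o_plain, f, tolerance = 1e-10)
})

test_that("gate comes from the auxiliary head entropy and is deterministic", {
  set.seed(25)
  N <- 15; C <- 5
  coords <- matrix(rnorm(N * 3), N, 3)
  f <- matrix(rnorm(N * C), N, C)
  params <- pg_init(C, 3, pg_config(k = 4, hidden = 8))
  r1 <- pg_invfr_forward(f, coords, params)
  r2 <- pg_invfr_forward(f, coords, params)
  expect_identical(r1$features, r2$features)
  expect_equal(r1$gate, uncertainty_gate(r1$entropy))
  expect_true(all(r1$entropy >= 0 & r1$entropy <= log(3) + 1e-9))
  expect_error(pg_invfr_forward(f * NA, coords, params), "finite")
})

test_that("analytic gradients of the refinement match finite differences", {
  set.seed(26)
  N <- 5; C <- 4
  coords <- matrix(rnorm(N * 3), N, 3)
  f <- matrix(rnorm(N * C) * 0.5, N, C)
  params <- pg_init(C, 3, pg_config(k = 3, hidden = 6))
  gate <- pg_invfr_forward(f, coords, params)$gate   # freeze the gate
  ns$ag_begin()
  xn <- ns$ag_param(f)
  s <- ns$ag_sum(pg_invfr_forward(xn, coords, params, gate = gate)$features)
  ns$ag_backward(s)
  num <- fd_grad(function(x)
    sum(pg_invfr_forward(x, coords, params, gate = gate)$features), f)
  expect_lt(max(abs(xn$grad - num)) / max(abs(num)), 1e-4)
})
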