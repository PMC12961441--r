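# Independent oracles used by the tests. Each re-derives the quantity under
# test from its definition, without touching the package's implementation
# paths (plain loops, dense enumerations, closed forms).

ns <- asNamespace("ptv2fr")

# random labeled cloud
random_cloud <- function(n, seed = 1L) {
  set.seed(seed)
  labeled_cloud(matrix(rnorm(n * 3), n, 3),
                matrix(sample(0:255, n * 3, replace = TRUE), n, 3),
                sample(c(-1L, 0L, 1L, 2L), n, replace = TRUE),
                pot_id = paste0("p", seed))
}

# independent PLY writers (ASCII and binary), sharing no code with the package
oracle_write_ply_ascii <- function(cloud, path) {
  lines <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(cloud$points)),
             "property float x", "property float y", "property float z",
             "property uchar red", "property uchar green", "property uchar blue",
             "property int label", "end_header",
             paste(cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                   cloud$colors[, 1], cloud$colors[, 2], cloud$colors[, 3],
                   cloud$labels))
  writeLines(lines, path)
}

oracle_write_ply_binary <- function(cloud, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           paste("element vertex", nrow(cloud$points)),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "property int label", "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  for (i in seq_len(nrow(cloud$points))) {
    writeBin(as.numeric(cloud$points[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(cloud$colors[i, ]), con)
    writeBin(as.integer(cloud$labels[i]), con, size = 4, endian = "little")
  }
}

# greedy max-min FPS by exhaustive per-step search
oracle_fps <- function(points, m, start) {
  n <- nrow(points)
  sel <- integer(m)
  sel[1] <- start
  mind <- rep(Inf, n)
  for (s in seq_len(m)) {
    if (s > 1) sel[s] <- which.max(mind)
    for (j in seq_len(n)) {
      d <- sum((points[sel[s], ] - points[j, ])^2)
      if (d < mind[j]) mind[j] <- d
    }
  }
  sel
}

# textbook DBSCAN with explicit core/border/noise semantics, plain R
oracle_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  lab <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    frontier <- i
    lab[i] <- cl
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (p in frontier) {
        for (q in nb[[p]]) {
          if (lab[q] == 0L) {
            lab[q] <- cl
            if (core[q]) nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
  }
  lab[lab == 0L] <- -1L
  lab
}

# dense step-by-step dual-coordinate attention following the block's
# equations: per-pair logits assembled explicitly, full N x K score matrix
oracle_dca <- function(features, graph, coords, params) {
  val <- function(p) p$value
  N <- nrow(features); K <- graph$K; C <- ncol(features)
  relu <- function(x) pmax(x, 0)
  bn <- function(x, g, b) {
    mu <- colMeans(x); v <- colMeans(sweep(x, 2, mu)^2)
    sweep(sweep(sweep(sweep(x, 2, mu), 2, sqrt(v + 1e-5), `/`),
                2, val(g$gamma)[1, ], `*`), 2, val(g$beta)[1, ], `+`)
  }
  lin <- function(x, l) {
    y <- x %*% val(l$W)
    if (!is.null(l$b)) y <- sweep(y, 2, val(l$b)[1, ], `+`)
    y
  }
  mlp <- function(x, m) {
    for (i in seq_len(m$n)) {
      x <- lin(x, m$layers[[i]])
      if (i < m$n) x <- relu(x)
    }
    x
  }
  q <- relu(bn(lin(features, params$Wq), params$q_bn))
  k <- relu(bn(lin(features, params$Wk), params$k_bn))
  v <- lin(features, params$Wv)
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  pn <- coords
  for (c in 1:3) pn[, c] <- if (hi[c] > lo[c]) (coords[, c] - lo[c]) / (hi[c] - lo[c]) else 0
  alpha <- val(params$alpha)[1, 1]
  out <- matrix(0, N, C)
  for (i in seq_len(N)) {
    nbr <- graph$idx[i, ]
    df_all <- features[nbr, , drop = FALSE] - matrix(features[i, ], K, C, byrow = TRUE)
    pool <- c(colMeans(df_all), apply(df_all, 2, max))
    s <- numeric(K)
    for (jj in seq_len(K)) {
      j <- nbr[jj]
      dp <- coords[j, ] - coords[i, ]
      df <- features[j, ] - features[i, ]
      s[jj] <- sum(q[i, ] * k[j, ]) / sqrt(C) +
        mlp(matrix(c(dp, df), 1), params$psi_rel) +
        mlp(matrix(pn[i, ], 1), params$psi_abs) +
        alpha * mlp(matrix(pool, 1), params$psi_pool)
    }
    w <- exp(s - max(s)); w <- w / sum(w)
    out[i, ] <- colSums(v[nbr, , drop = FALSE] * w)
  }
  out
}

# dense kernel-generation oracle: [F_i, d_i] -> M_c -> ReLU -> M_k, row by row
oracle_kernels <- function(features, graph, geometry, params) {
  val <- function(p) p$value
  N <- nrow(features)
  H <- matrix(0, N, graph$K)
  for (i in seq_len(N)) {
    x <- c(features[i, ], geometry[i, ])
    h <- pmax(x %*% val(params$Mc$W) + val(params$Mc$b)[1, ], 0)
    H[i, ] <- h %*% val(params$Mk$W) + val(params$Mk$b)[1, ]
  }
  H
}

# definitional Lovasz extension via the telescoping Jaccard sum:
# loss_c = sum_k e_{pi(k)} * (J(k) - J(k-1)), J(k) the Jaccard loss of the
# top-k error set against the ground-truth set
oracle_lovasz <- function(probs, labels) {
  classes <- sort(unique(labels))
  total <- 0
  for (cc in classes) {
    fg <- labels == cc
    e <- ifelse(fg, 1 - probs[, cc + 1], probs[, cc + 1])
    ord <- order(e, decreasing = TRUE)
    jacc <- function(k) {
      # Jaccard loss between ground truth and the union of gt with top-k errors
      topk <- ord[seq_len(k)]
      inter <- sum(fg & !(seq_along(fg) %in% topk))
      uni <- sum(fg | (seq_along(fg) %in% topk))
      1 - inter / uni
    }
    lc <- 0
    prev <- 0
    for (k in seq_along(ord)) {
      jk <- jacc(k)
      lc <- lc + e[ord[k]] * (jk - prev)
      prev <- jk
    }
    total <- total + lc
  }
  total / length(classes)
}

# full C x C confusion-matrix metric oracle
oracle_metrics <- function(pred, truth, C = 3L) {
  keep <- truth != -1L
  p <- pred[keep]; t <- truth[keep]
  cm <- matrix(0L, C, C)
  for (i in seq_along(p)) cm[t[i] + 1L, p[i] + 1L] <- cm[t[i] + 1L, p[i] + 1L] + 1L
  res <- data.frame(precision = numeric(C), recall = numeric(C),
                    f1 = numeric(C), iou = numeric(C))
  for (c in seq_len(C)) {
    tp <- cm[c, c]; fp <- sum(cm[, c]) - tp; fn <- sum(cm[c, ]) - tp
    res$precision[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    res$recall[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    res$f1[c] <- if (res$precision[c] + res$recall[c] > 0)
      2 * res$precision[c] * res$recall[c] / (res$precision[c] + res$recall[c]) else 0
    res$iou[c] <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
  }
  res
}

# central finite difference of f at x (matrix), elementwise
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    xp <- x; xp[i, j] <- xp[i, j] + eps
    xm <- x; xm[i, j] <- xm[i, j] - eps
    g[i, j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# compact network profile used by training tests (reduced widths)
desk_small_config <- function(...) {
  ptv2fr_config(channels = c(16L, 32L),
                mrdca = mrdca_config(k = c(4L, 8L, 12L), branch_channels = 8L),
                pg = pg_config(k = 8L, hidden = 16L), ...)
}

# zero out every parameter of a module (for degenerate-configuration tests)
zero_params <- function(module) {
  for (p in ns$nn_params(module)) p$value[] <- 0
  invisible(module)
}
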