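# Minimal tape-based reverse-mode automatic differentiation on dense matrices.
#
# Nodes are environments holding $value (a matrix), $grad, $parents and a
# $backward closure. Operations append to a package-level tape; only nodes
# that (transitively) depend on a parameter are recorded, so pure inference
# builds no tape. ag_backward() walks the tape in reverse, accumulating
# gradients into parameter nodes, which persist across tapes until an
# optimizer step consumes them.
#
# The op set is exactly what the attention/refinement blocks need: matrix
# product, broadcast add, elementwise arithmetic, ReLU/sigmoid, column
# concat/select, row gather/scatter (neighbor indexing), grouped softmax and
# max/mean pooling over fixed-size neighbor lists, per-cloud batch
# normalization, row/column reductions, and fused loss heads.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$len <- 0L

#' @keywords internal
ag_begin <- function() {
  .ag$tape <- vector("list", 512L)
  .ag$len <- 0L
  invisible(NULL)
}

.ag_push <- function(n) {
  L <- .ag$len + 1L
  if (L > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[L]] <- n
  .ag$len <- L
  n
}

.ag_node <- function(value, parents, backward) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$req <- FALSE
  for (p in parents) if (isTRUE(p$req)) { e$req <- TRUE; break }
  if (e$req) {
    e$parents <- parents
    e$backward <- backward
    .ag_push(e)
  }
  e
}

#' @keywords internal
ag_const <- function(v) {
  e <- new.env(parent = emptyenv())
  e$value <- if (is.matrix(v)) v else as.matrix(v)
  e$grad <- NULL
  e$req <- FALSE
  e
}

#' @keywords internal
ag_param <- function(v, no_decay = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- if (is.matrix(v)) v else as.matrix(v)
  e$grad <- NULL
  e$req <- TRUE
  e$param <- TRUE
  e$no_decay <- no_decay
  e
}

.acc <- function(p, g) {
  if (isTRUE(p$req)) {
    if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  }
  invisible(NULL)
}

#' @keywords internal
ag_value <- function(x) if (is.environment(x)) x$value else x

.as_node <- function(x) if (is.environment(x)) x else ag_const(x)

#' @keywords internal
ag_backward <- function(loss) {
  loss$grad <- matrix(1, 1, 1)
  if (.ag$len > 0L) for (i in .ag$len:1L) {
    n <- .ag$tape[[i]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n)
  }
  invisible(NULL)
}

# ---- elementary ops -------------------------------------------------------

ag_mm <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  .ag_node(a$value %*% b$value, list(a, b), function(n) {
    .acc(n$parents[[1]], n$grad %*% t(n$parents[[2]]$value))
    .acc(n$parents[[2]], t(n$parents[[1]]$value) %*% n$grad)
  })
}

# b may be a 1 x C bias broadcast over the rows of a
ag_add <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  bias <- nrow(b$value) == 1L && nrow(a$value) > 1L
  val <- if (bias) sweep(a$value, 2L, b$value[1L, ], `+`) else a$value + b$value
  .ag_node(val, list(a, b), function(n) {
    .acc(n$parents[[1]], n$grad)
    if (bias) .acc(n$parents[[2]], matrix(colSums(n$grad), 1L))
    else .acc(n$parents[[2]], n$grad)
  })
}

ag_sub <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  .ag_node(a$value - b$value, list(a, b), function(n) {
    .acc(n$parents[[1]], n$grad)
    .acc(n$parents[[2]], -n$grad)
  })
}

ag_mul <- function(a, b) {   # elementwise, same shape
  a <- .as_node(a); b <- .as_node(b)
  .ag_node(a$value * b$value, list(a, b), function(n) {
    .acc(n$parents[[1]], n$grad * n$parents[[2]]$value)
    .acc(n$parents[[2]], n$grad * n$parents[[1]]$value)
  })
}

ag_smul <- function(a, s) {  # multiply by a plain scalar
  a <- .as_node(a)
  .ag_node(a$value * s, list(a), function(n) .acc(n$parents[[1]], n$grad * s))
}

ag_pmul <- function(a, alpha) {  # multiply by a 1x1 parameter (learnable gate)
  a <- .as_node(a); alpha <- .as_node(alpha)
  av <- alpha$value[1L, 1L]
  .ag_node(a$value * av, list(a, alpha), function(n) {
    .acc(n$parents[[1]], n$grad * n$parents[[2]]$value[1L, 1L])
    .acc(n$parents[[2]], matrix(sum(n$grad * n$parents[[1]]$value), 1L, 1L))
  })
}

ag_relu <- function(a) {
  a <- .as_node(a)
  .ag_node(pmax(a$value, 0), list(a), function(n)
    .acc(n$parents[[1]], n$grad * (n$parents[[1]]$value > 0)))
}

ag_sigmoid <- function(a) {
  a <- .as_node(a)
  s <- 1 / (1 + exp(-a$value))
  .ag_node(s, list(a), function(n)
    .acc(n$parents[[1]], n$grad * n$value * (1 - n$value)))
}

ag_concat_cols <- function(lst) {
  lst <- lapply(lst, .as_node)
  widths <- vapply(lst, function(x) ncol(x$value), integer(1))
  val <- do.call(cbind, lapply(lst, `[[`, "value"))
  .ag_node(val, lst, function(n) {
    off <- 0L
    for (i in seq_along(n$parents)) {
      .acc(n$parents[[i]], n$grad[, (off + 1L):(off + widths[i]), drop = FALSE])
      off <- off + widths[i]
    }
  })
}

ag_cols <- function(a, idx) {
  a <- .as_node(a)
  .ag_node(a$value[, idx, drop = FALSE], list(a), function(n) {
    g <- matrix(0, nrow(n$parents[[1]]$value), ncol(n$parents[[1]]$value))
    g[, idx] <- n$grad
    .acc(n$parents[[1]], g)
  })
}

.scatter_rows <- function(g, idx, n) {
  rs <- rowsum(g, group = idx)
  out <- matrix(0, n, ncol(g))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

ag_rows <- function(a, idx) {  # gather rows
  a <- .as_node(a)
  .ag_node(a$value[idx, , drop = FALSE], list(a), function(n)
    .acc(n$parents[[1]], .scatter_rows(n$grad, idx, nrow(n$parents[[1]]$value))))
}

ag_rowsum_group <- function(a, group, ngroups) {  # scatter-add rows by group id
  a <- .as_node(a)
  .ag_node(.scatter_rows(a$value, group, ngroups), list(a), function(n)
    .acc(n$parents[[1]], n$grad[group, , drop = FALSE]))
}

ag_rowsums <- function(a) {    # N x C -> N x 1
  a <- .as_node(a)
  .ag_node(matrix(rowSums(a$value), ncol = 1L), list(a), function(n)
    .acc(n$parents[[1]], matrix(n$grad[, 1L], nrow(n$parents[[1]]$value),
                                ncol(n$parents[[1]]$value))))
}

ag_sum <- function(a) {        # -> 1 x 1
  a <- .as_node(a)
  .ag_node(matrix(sum(a$value), 1L, 1L), list(a), function(n)
    .acc(n$parents[[1]], matrix(n$grad[1L, 1L], nrow(n$parents[[1]]$value),
                                ncol(n$parents[[1]]$value))))
}

# multiply every row of x (M x C) by the matching entry of w (M x 1)
ag_rows_times_colvec <- function(x, w) {
  x <- .as_node(x); w <- .as_node(w)
  .ag_node(x$value * w$value[, 1L], list(x, w), function(n) {
    .acc(n$parents[[1]], n$grad * n$parents[[2]]$value[, 1L])
    .acc(n$parents[[2]], matrix(rowSums(n$grad * n$parents[[1]]$value), ncol = 1L))
  })
}

# softmax within consecutive groups of K rows of a (N*K) x 1 score vector
ag_group_softmax <- function(score, K) {
  score <- .as_node(score)
  s <- matrix(score$value[, 1L], nrow = K)
  s <- sweep(s, 2L, apply(s, 2L, max))
  e <- exp(s)
  w <- sweep(e, 2L, colSums(e), `/`)
  .ag_node(matrix(as.vector(w), ncol = 1L), list(score), function(n) {
    gw <- matrix(n$grad[, 1L], nrow = K)
    wv <- matrix(n$value[, 1L], nrow = K)
    ds <- wv * sweep(gw, 2L, colSums(gw * wv))
    .acc(n$parents[[1]], matrix(as.vector(ds), ncol = 1L))
  })
}

# per-group, per-channel max over consecutive groups of K rows: (N*K) x C -> N x C
ag_group_maxpool <- function(a, K) {
  a <- .as_node(a)
  M <- nrow(a$value); C <- ncol(a$value); N <- M %/% K
  val <- matrix(0, N, C)
  arg <- matrix(0L, N, C)          # flat row index of each max
  for (c in seq_len(C)) {
    m <- matrix(a$value[, c], nrow = K)
    i <- max.col(t(m), ties.method = "first")
    arg[, c] <- (seq_len(N) - 1L) * K + i
    val[, c] <- m[cbind(i, seq_len(N))]
  }
  .ag_node(val, list(a), function(n) {
    g <- matrix(0, M, C)
    for (c in seq_len(C)) g[arg[, c], c] <- g[arg[, c], c] + n$grad[, c]
    .acc(n$parents[[1]], g)
  })
}

# per-channel standardization over the points of one cloud with learned affine
ag_pointbn <- function(x, gamma, beta, eps = 1e-5) {
  x <- .as_node(x); gamma <- .as_node(gamma); beta <- .as_node(beta)
  N <- nrow(x$value)
  mu <- colMeans(x$value)
  xc <- sweep(x$value, 2L, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  val <- sweep(sweep(xhat, 2L, gamma$value[1L, ], `*`), 2L, beta$value[1L, ], `+`)
  .ag_node(val, list(x, gamma, beta), function(n) {
    g <- n$grad
    dxhat <- sweep(g, 2L, gamma$value[1L, ], `*`)
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * xhat)
    dx <- sweep(dxhat, 2L, t1 / N) - sweep(xhat, 2L, t2 / N, `*`)
    dx <- sweep(dx, 2L, istd, `*`)
    .acc(n$parents[[1]], dx)
    .acc(n$parents[[2]], matrix(colSums(g * xhat), 1L))
    .acc(n$parents[[3]], matrix(colSums(g), 1L))
  })
}

ag_log_softmax <- function(x) {  # row-wise
  x <- .as_node(x)
  mx <- apply(x$value, 1L, max)
  sh <- x$value - mx
  lse <- log(rowSums(exp(sh)))
  val <- sh - lse
  .ag_node(val, list(x), function(n) {
    sm <- exp(n$value)
    .acc(n$parents[[1]], n$grad - sm * rowSums(n$grad))
  })
}

ag_softmax_rows <- function(x) {
  x <- .as_node(x)
  mx <- apply(x$value, 1L, max)
  e <- exp(x$value - mx)
  sm <- e / rowSums(e)
  .ag_node(sm, list(x), function(n)
    .acc(n$parents[[1]], n$value * (n$grad - rowSums(n$grad * n$value))))
}

ag_detach <- function(x) ag_const(.as_node(x)$value)

# N x K -> (N*K) x 1 in row-major order (neighbor slot fastest), matching the
# rep(seq_len(N), each = K) pair layout used by the graph ops
ag_flatten_rows <- function(x) {
  x <- .as_node(x)
  K <- ncol(x$value)
  .ag_node(matrix(as.vector(t(x$value)), ncol = 1L), list(x), function(n)
    .acc(n$parents[[1]], matrix(n$grad[, 1L], ncol = K, byrow = TRUE)))
}

# ---- optimizer ------------------------------------------------------------

# AdamW: decoupled weight decay, bias-corrected moments. `params` is a flat
# list of parameter nodes; state lives on the nodes.
adamw_step <- function(params, lr, step, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.05) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$adam_m)) { p$adam_m <- g * 0; p$adam_v <- g * 0 }
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * g
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * g^2
    mhat <- p$adam_m / (1 - beta1^step)
    vhat <- p$adam_v / (1 - beta2^step)
    upd <- mhat / (sqrt(vhat) + eps)
    if (!isTRUE(p$no_decay)) upd <- upd + weight_decay * p$value
    p$value <- p$value - lr * upd
    p$grad <- NULL
  }
  invisible(NULL)
}

# zero accumulated gradients without stepping
ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# recursively collect parameter nodes from nested module lists
nn_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (isTRUE(x$param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  out
}
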