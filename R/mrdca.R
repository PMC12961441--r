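# Multi-Radius Dual-Coordinate Attention (MRDCA).
#
# Three parallel KNN branches (fine/medium/coarse neighborhoods, K = 8/16/24
# by default) each run dual-coordinate attention: scalar attention logits mix
# a scaled query-key product, an MLP of the relative offset and feature
# difference (psi_rel), an MLP of per-cloud min-max-normalized absolute
# coordinates (psi_abs), and a learnable-gated MLP of neighborhood-pooled
# channel statistics (psi_pool). Branch outputs are concatenated (or summed)
# and fused by a linear layer with BN + ReLU.

#' Build a k-nearest-neighbor graph
#'
#' Each point's neighbor list holds its K nearest points by Euclidean
#' distance (self included, distances non-decreasing, ties to the lower
#' index). Clouds with fewer than K points pad the lists with the query's own
#' index.
#'
#' @param points numeric N x 3 coordinate matrix.
#' @param K neighborhood size (>= 1).
#' @return a `neighbor_graph`: list with `idx` (N x K integer matrix of
#'   1-based neighbor indices), `K`, and the query `points`.
#' @export
build_knn_graph <- function(points, K) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("cannot build a KNN graph on an empty cloud")
  if (K < 1L) stop("`K` must be >= 1")
  structure(list(idx = cpp_knn(points, as.integer(K)), K = as.integer(K),
                 points = points),
            class = "neighbor_graph")
}

#' MRDCA configuration
#'
#' @param k integer vector of per-branch neighbor counts, default `c(8,16,24)`.
#' @param branch_channels channels per branch, default 16.
#' @param fusion branch aggregation, `"concat"` (default) or `"sum"`.
#' @return an `mrdca_config` list.
#' @export
mrdca_config <- function(k = c(8L, 16L, 24L), branch_channels = 16L,
                         fusion = c("concat", "sum")) {
  fusion <- match.arg(fusion)
  stopifnot(all(k >= 1L), branch_channels >= 1L)
  structure(list(k = as.integer(k), branch_channels = as.integer(branch_channels),
                 fusion = fusion),
            class = "mrdca_config")
}

#' Initialize MRDCA parameters
#'
#' @param d_in input feature width.
#' @param d_out output feature width.
#' @param config an [mrdca_config()].
#' @return parameter container (nested list of parameter nodes).
#' @export
mrdca_init <- function(d_in, d_out, config = mrdca_config()) {
  bc <- config$branch_channels
  nb <- length(config$k)
  branches <- lapply(seq_len(nb), function(b) {
    list(Wq = nn_linear(bc, bc), q_bn = nn_bn(bc),
         Wk = nn_linear(bc, bc), k_bn = nn_bn(bc),
         Wv = nn_linear(bc, bc, bias = FALSE),
         psi_rel = nn_mlp(c(3L + bc, bc, 1L)),
         psi_abs = nn_mlp(c(3L, bc, 1L)),
         psi_pool = nn_mlp(c(2L * bc, bc, 1L)),
         alpha = ag_param(matrix(0, 1L, 1L), no_decay = TRUE))
  })
  fuse_in <- if (config$fusion == "concat") nb * bc else bc
  list(proj = nn_lbr(d_in, nb * bc),
       branches = branches,
       fuse = nn_lbr(fuse_in, d_out),
       config = config, d_in = d_in, d_out = d_out)
}

# min-max normalized absolute coordinates; a degenerate (constant) axis maps
# to 0 rather than NaN
.norm_coords <- function(coords) {
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  rng <- hi - lo
  out <- sweep(coords, 2L, lo)
  for (c in seq_len(ncol(coords)))
    out[, c] <- if (rng[c] > 0) out[, c] / rng[c] else 0
  out
}

#' Dual-coordinate attention over one neighbor graph
#'
#' Computes, for every query i and neighbor j, the attention logit
#' `q_i . k_j / sqrt(d) + psi_rel(dp_ij, df_ij) + psi_abs(p_i^norm) +
#' alpha * psi_pool(pooled df)` followed by a per-query softmax, and returns
#' the weighted sum of value vectors.
#'
#' @param features N x C feature matrix (or autodiff node), C = branch width.
#' @param graph a [build_knn_graph()] result.
#' @param coords N x 3 coordinates.
#' @param params one element of `mrdca_init()$branches`.
#' @param return_weights also return the N x K attention weight matrix.
#' @return N x C enhanced features (matrix when `features` was a matrix),
#'   or a list with `features` and `weights` when `return_weights = TRUE`.
#' @export
dca_attention <- function(features, graph, coords, params,
                          return_weights = FALSE) {
  as_matrix <- !is.environment(features)
  f <- .as_node(features)
  if (!all(is.finite(f$value))) stop("non-finite features")
  N <- nrow(f$value); K <- graph$K
  ctr <- rep(seq_len(N), each = K)
  nbr <- as.vector(t(graph$idx))

  q <- ag_relu(nn_bn_forward(params$q_bn, nn_linear_forward(params$Wq, f)))
  k <- ag_relu(nn_bn_forward(params$k_bn, nn_linear_forward(params$Wk, f)))
  v <- nn_linear_forward(params$Wv, f)

  qc <- ag_rows(q, ctr); kn <- ag_rows(k, nbr)
  s_qk <- ag_smul(ag_rowsums(ag_mul(qc, kn)), 1 / sqrt(ncol(f$value)))

  dp <- ag_const(coords[nbr, , drop = FALSE] - coords[ctr, , drop = FALSE])
  df <- ag_sub(ag_rows(f, nbr), ag_rows(f, ctr))
  s_rel <- nn_mlp_forward(params$psi_rel, ag_concat_cols(list(dp, df)))

  pn <- ag_const(.norm_coords(coords))
  s_abs <- ag_rows(nn_mlp_forward(params$psi_abs, pn), ctr)

  pool_mean <- ag_smul(ag_rowsum_group(df, ctr, N), 1 / K)
  pool_max <- ag_group_maxpool(df, K)
  s_pool <- nn_mlp_forward(params$psi_pool, ag_concat_cols(list(pool_mean, pool_max)))
  s_pool <- ag_rows(ag_pmul(s_pool, params$alpha), ctr)

  logits <- ag_add(ag_add(s_qk, s_rel), ag_add(s_abs, s_pool))
  w <- ag_group_softmax(logits, K)
  out <- ag_rowsum_group(ag_rows_times_colvec(ag_rows(v, nbr), w), ctr, N)

  res <- if (as_matrix) out$value else out
  if (return_weights) {
    list(features = res, weights = matrix(w$value[, 1L], nrow = N, byrow = TRUE))
  } else res
}

#' MRDCA forward pass
#'
#' Projects input features to the aligned width, splits them into the
#' per-branch channel groups, runs [dca_attention()] per branch on that
#' branch's KNN graph, aggregates the branch outputs (concatenation or
#' summation) and fuses them with a linear + BN + ReLU stage.
#'
#' @param features N x d_in matrix (or autodiff node).
#' @param coords N x 3 coordinates.
#' @param params from [mrdca_init()].
#' @param graphs optional list of precomputed [build_knn_graph()] results,
#'   one per branch (they are built from `coords` otherwise).
#' @return N x d_out features (matrix when `features` was a matrix).
#' @export
mrdca_forward <- function(features, coords, params, graphs = NULL) {
  as_matrix <- !is.environment(features)
  f <- .as_node(features)
  if (ncol(f$value) != params$d_in)
    stop(sprintf("feature width %d does not match module input width %d",
                 ncol(f$value), params$d_in))
  cfg <- params$config
  bc <- cfg$branch_channels
  fp <- nn_lbr_forward(params$proj, f)
  enh <- vector("list", length(cfg$k))
  for (b in seq_along(cfg$k)) {
    graph <- if (is.null(graphs)) build_knn_graph(coords, cfg$k[b]) else graphs[[b]]
    fb <- ag_cols(fp, ((b - 1L) * bc + 1L):(b * bc))
    enh[[b]] <- dca_attention(fb, graph, coords, params$branches[[b]])
  }
  agg <- if (cfg$fusion == "concat") ag_concat_cols(enh) else {
    s <- enh[[1L]]
    for (b in seq_along(enh)[-1L]) s <- ag_add(s, enh[[b]])
    s
  }
  out <- nn_lbr_forward(params$fuse, agg)
  if (as_matrix) out$value else out
}
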