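# Point-Graph Involution Feature Refinement (PG-InvFR).
#
# Involution uses spatially varying, channel-shared dynamic kernels; here the
# image grid is replaced by a k-NN point-graph neighborhood. For each point a
# small MLP stack (M_c then M_k) generates one kernel weight per neighbor
# slot from the point's features together with directional geometric cues
# (per-neighbor distances and the local principal direction). The refinement
# output is an entropy-gated weighted sum of neighbor features: points whose
# auxiliary class distribution is uncertain (high entropy, typically organ
# boundaries) receive a stronger refinement. Applied between the decoder
# output and the segmentation head.

#' Per-point Shannon entropy of class probabilities
#'
#' `U_i = -sum_c p_ic log p_ic` (natural log, `0 log 0 = 0`), the uncertainty
#' measure feeding the refinement gate. Bounded by `log(C)`.
#'
#' @param probs N x C matrix; each row a probability vector (tolerance 1e-6).
#' @return numeric vector of N entropies.
#' @export
point_entropy <- function(probs) {
  probs <- as.matrix(probs)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  pl <- probs * log(probs)
  pl[probs == 0] <- 0
  -rowSums(pl)
}

#' Entropy-derived uncertainty gate
#'
#' `alpha_i = sigmoid(U_i)`, strictly increasing in the entropy; uniform
#' predictions gate harder refinement than confident ones.
#'
#' @param entropy non-negative numeric vector.
#' @return numeric vector of gates in (0, 1).
#' @export
uncertainty_gate <- function(entropy) {
  if (any(entropy < 0)) stop("entropy must be non-negative")
  1 / (1 + exp(-entropy))
}

#' PG-InvFR configuration
#'
#' @param k neighborhood size of the point graph, default 16.
#' @param residual add the refinement to the input features (default TRUE) so
#'   an untrained module preserves the decoder output.
#' @param aux_head_weight weight of the auxiliary classifier loss during
#'   joint training, default 0.4.
#' @param hidden hidden width of the kernel-generation MLP, default 32.
#' @param ball_radius optional radius; when set, the graph keeps only
#'   neighbors within this distance (others fall back to the self index).
#' @param neighborhood_mean average class probabilities over the neighborhood
#'   before the entropy (default FALSE: pointwise).
#' @param iterations number of refinement passes, default 1.
#' @return a `pg_config` list.
#' @export
pg_config <- function(k = 16L, residual = TRUE, aux_head_weight = 0.4,
                      hidden = 32L, ball_radius = NULL,
                      neighborhood_mean = FALSE, iterations = 1L) {
  structure(list(k = as.integer(k), residual = residual,
                 aux_head_weight = aux_head_weight, hidden = as.integer(hidden),
                 ball_radius = ball_radius, neighborhood_mean = neighborhood_mean,
                 iterations = as.integer(iterations)),
            class = "pg_config")
}

#' Initialize PG-InvFR parameters
#'
#' @param d feature width of the decoder output.
#' @param num_classes classes of the auxiliary classifier, default 3.
#' @param config a [pg_config()].
#' @return parameter container.
#' @export
pg_init <- function(d, num_classes = 3L, config = pg_config()) {
  K <- config$k
  list(aux = nn_linear(d, num_classes),
       Mc = nn_linear(d + K + 3L, config$hidden),
       Mk = nn_linear(config$hidden, K),
       config = config, d = d, num_classes = num_classes)
}

# Directional geometric cues d_i: per-neighbor Euclidean distances (K
# columns) concatenated with the neighborhood's unit principal direction
# (top eigenvector of the local covariance, sign fixed to non-negative z).
.pg_geometry <- function(graph) {
  pts <- graph$points
  N <- nrow(pts); K <- graph$K
  nbr <- as.vector(t(graph$idx))
  ctr <- rep(seq_len(N), each = K)
  diff <- pts[nbr, , drop = FALSE] - pts[ctr, , drop = FALSE]
  dist <- matrix(sqrt(rowSums(diff^2)), ncol = K, byrow = TRUE)
  dir <- matrix(0, N, 3L)
  for (i in seq_len(N)) {
    d <- diff[((i - 1L) * K + 1L):(i * K), , drop = FALSE]
    ev <- eigen(crossprod(d) / K, symmetric = TRUE)
    v <- ev$vectors[, 1L]
    if (v[3L] < 0) v <- -v
    dir[i, ] <- v
  }
  cbind(dist, dir)
}

#' Generate per-point dynamic kernels
#'
#' `H_i = M_k(M_c([F_i, d_i]))`: one kernel weight per neighbor slot,
#' conditioned on the point's features and its directional geometry.
#'
#' @param features N x C matrix (or autodiff node).
#' @param graph a [build_knn_graph()] result with `K` matching the params.
#' @param geometry N x (K+3) geometric cue matrix, or NULL to compute it from
#'   the graph.
#' @param params from [pg_init()].
#' @return N x K kernel field (matrix when `features` was a matrix).
#' @export
generate_kernels <- function(features, graph, geometry = NULL, params) {
  as_matrix <- !is.environment(features)
  f <- .as_node(features)
  if (is.null(geometry)) geometry <- .pg_geometry(graph)
  if (ncol(geometry) != params$config$k + 3L)
    stop("geometry has the wrong number of neighbor slots")
  if (graph$K != params$config$k) stop("graph K does not match kernel slots")
  inp <- ag_concat_cols(list(f, ag_const(geometry)))
  H <- nn_linear_forward(params$Mk, ag_relu(nn_linear_forward(params$Mc, inp)))
  if (as_matrix) H$value else H
}

#' Entropy-gated kernel refinement
#'
#' `f_i^out = alpha_i * sum_j H_ij f_j` over the point graph; the dynamic
#' kernel weighs each neighbor, the gate scales the refinement per point.
#'
#' @param features N x C matrix (or node).
#' @param kernel_field N x K matrix (or node) from [generate_kernels()].
#' @param gate numeric vector of N gates from [uncertainty_gate()].
#' @param graph the point graph the kernels were generated on.
#' @return N x C refined features (matrix when inputs were matrices).
#' @export
refine_features <- function(features, kernel_field, gate, graph) {
  as_matrix <- !is.environment(features) && !is.environment(kernel_field)
  f <- .as_node(features)
  H <- .as_node(kernel_field)
  if (!all(is.finite(H$value))) stop("non-finite kernel weights")
  N <- nrow(f$value); K <- graph$K
  ctr <- rep(seq_len(N), each = K)
  nbr <- as.vector(t(graph$idx))
  Hf <- ag_flatten_rows(H)
  agg <- ag_rowsum_group(ag_rows_times_colvec(ag_rows(f, nbr), Hf), ctr, N)
  out <- ag_rows_times_colvec(agg, ag_const(matrix(gate, ncol = 1L)))
  if (as_matrix) out$value else out
}

#' PG-InvFR forward pass
#'
#' Full refinement pipeline: auxiliary linear classifier on the decoder
#' features -> softmax class probabilities (excluded from gradient flow into
#' the gate) -> entropy -> sigmoid gate -> dynamic kernels -> gated weighted
#' neighbor sum, optionally added residually to the input.
#'
#' @param decoder_features N x d matrix (or node) of decoder output features.
#' @param coords N x 3 coordinates.
#' @param params from [pg_init()].
#' @param gate optional numeric vector overriding the entropy-derived gate
#'   (used for diagnostics and controlled experiments).
#' @param graph,geometry optional precomputed point graph and geometric cues
#'   (built from `coords` otherwise).
#' @return a list with `features` (refined, N x d; matrix when the input was
#'   a matrix), `aux_logits` (for the auxiliary loss), `entropy`, and `gate`.
#' @export
pg_invfr_forward <- function(decoder_features, coords, params, gate = NULL,
                             graph = NULL, geometry = NULL) {
  as_matrix <- !is.environment(decoder_features)
  f <- .as_node(decoder_features)
  if (!all(is.finite(f$value))) stop("non-finite decoder features")
  cfg <- params$config
  if (is.null(graph)) {
    graph <- build_knn_graph(coords, cfg$k)
    if (!is.null(cfg$ball_radius)) {
      # ball-query semantics: neighbor slots beyond the radius fall back to self
      N <- nrow(coords)
      d <- sqrt(rowSums((coords[as.vector(t(graph$idx)), , drop = FALSE] -
                         coords[rep(seq_len(N), each = cfg$k), , drop = FALSE])^2))
      dm <- matrix(d, ncol = cfg$k, byrow = TRUE)
      graph$idx[dm > cfg$ball_radius] <- row(graph$idx)[dm > cfg$ball_radius]
    }
  }
  if (is.null(geometry)) geometry <- .pg_geometry(graph)
  aux_logits <- nn_linear_forward(params$aux, f)
  entropy <- NULL
  if (is.null(gate)) {
    probs <- exp(ag_log_softmax(ag_detach(aux_logits))$value)
    if (cfg$neighborhood_mean) {
      acc <- rowsum(probs[as.vector(t(graph$idx)), , drop = FALSE],
                    rep(seq_len(nrow(probs)), each = cfg$k))
      probs <- acc / cfg$k
    }
    entropy <- point_entropy(probs)
    gate <- uncertainty_gate(entropy)
  }
  out <- f
  for (it in seq_len(cfg$iterations)) {
    H <- generate_kernels(out, graph, geometry, params)
    ref <- refine_features(out, H, gate, graph)
    out <- if (cfg$residual) ag_add(out, ref) else ref
  }
  list(features = if (as_matrix) out$value else out,
       aux_logits = if (as_matrix) aux_logits$value else aux_logits,
       entropy = entropy, gate = gate)
}
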