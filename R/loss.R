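# Composite training loss: inverse-frequency weighted cross-entropy plus
# multiclass Lovasz-softmax (the Lovasz extension of the Jaccard loss),
# combined linearly with weights alpha and beta. Stems are a small minority
# of the points, so plain CE under-trains the stem class; the weighted CE
# rebalances classes and the Lovasz term optimizes region/IoU consistency.

#' Loss configuration
#'
#' @param alpha weight of the weighted cross-entropy term, default 1.
#' @param beta weight of the Lovasz-softmax term, default 1.
#' @param class_weights per-class CE weights; `NULL` (unit weights) or a
#'   positive numeric vector of length `num_classes`. Training computes them
#'   from label frequencies via [class_weights_from_frequency()].
#' @param ignore_label label excluded from the loss, default -1.
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 1, beta = 1, class_weights = NULL,
                        ignore_label = -1L) {
  if (alpha < 0 || beta < 0 || (alpha == 0 && beta == 0))
    stop("alpha and beta must be non-negative and not both zero")
  if (!is.null(class_weights) && any(class_weights <= 0))
    stop("class weights must be positive")
  structure(list(alpha = alpha, beta = beta, class_weights = class_weights,
                 ignore_label = as.integer(ignore_label)),
            class = "loss_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (C * N_c)` over the pooled (typically FPS-downsampled
#' training) labels, normalized to mean 1; ignore labels are excluded from
#' the counts. Doubling all counts leaves the weights unchanged.
#'
#' @param labels integer vector (or list of vectors) of labels in
#'   \{-1, 0, ..., C-1\}.
#' @param num_classes number of classes C, default 3.
#' @return numeric vector of C weights with mean 1.
#' @export
class_weights_from_frequency <- function(labels, num_classes = 3L) {
  labels <- unlist(labels, use.names = FALSE)
  labels <- labels[labels >= 0L]
  counts <- tabulate(labels + 1L, nbins = num_classes)
  if (any(counts == 0L))
    stop("class ", paste(which(counts == 0L) - 1L, collapse = ", "),
         " absent from the label collection")
  w <- sum(counts) / (num_classes * counts)
  w / mean(w)
}

# fused negative log-likelihood pick: L = sum_i w_i * (-lsm[i, y_i]) / sum w
.ag_nll_pick <- function(lsm, y, w) {
  lsm <- .as_node(lsm)
  idx <- cbind(seq_along(y), y + 1L)
  W <- sum(w)
  val <- matrix(sum(-w * lsm$value[idx]) / W, 1L, 1L)
  .ag_node(val, list(lsm), function(n) {
    g <- matrix(0, nrow(lsm$value), ncol(lsm$value))
    g[idx] <- -w / W
    .acc(n$parents[[1]], g * n$grad[1L, 1L])
  })
}

#' Class-weighted cross-entropy
#'
#' Mean over non-ignored points of `w_{y_i} * (-log softmax(logit_i)[y_i])`,
#' normalized by the sum of the applied weights (keeps the scale stable under
#' imbalance). Ignored points contribute nothing.
#'
#' @param logits N x C matrix (or autodiff node).
#' @param labels integer vector in \{-1, 0, ..., C-1\}.
#' @param class_weights length-C positive weights; `NULL` for unit weights.
#' @param ignore_label default -1.
#' @return scalar loss (numeric for matrix input, 1 x 1 node for node input).
#' @export
weighted_cross_entropy <- function(logits, labels, class_weights = NULL,
                                   ignore_label = -1L) {
  as_matrix <- !is.environment(logits)
  lg <- .as_node(logits)
  C <- ncol(lg$value)
  if (is.null(class_weights)) class_weights <- rep(1, C)
  valid <- which(labels != ignore_label)
  if (length(valid) == 0L) stop("all points carry the ignore label")
  y <- labels[valid]
  if (any(y < 0L | y >= C)) stop("labels out of range")
  lsm <- ag_log_softmax(ag_rows(lg, valid))
  out <- .ag_nll_pick(lsm, y, class_weights[y + 1L])
  if (as_matrix) out$value[1L, 1L] else out
}

# Jaccard-gradient vector of a sorted ground-truth indicator (the Lovasz
# extension gradient)
.lovasz_grad <- function(fg_sorted) {
  gts <- sum(fg_sorted)
  inter <- gts - cumsum(fg_sorted)
  union <- gts + cumsum(1 - fg_sorted)
  jac <- 1 - inter / union
  n <- length(fg_sorted)
  if (n > 1L) jac[2:n] <- jac[2:n] - jac[1:(n - 1L)]
  jac
}

# fused Lovasz-softmax on valid rows; returns (value, grad wrt probs) logic
.ag_lovasz <- function(probs, y) {
  probs <- .as_node(probs)
  P <- probs$value
  n <- nrow(P)
  classes <- sort(unique(y))
  loss <- 0
  gP <- matrix(0, n, ncol(P))
  for (c in classes) {
    fg <- as.numeric(y == c)
    pc <- P[, c + 1L]
    e <- ifelse(fg == 1, 1 - pc, pc)
    ord <- order(e, decreasing = TRUE)
    jac <- .lovasz_grad(fg[ord])
    loss <- loss + sum(e[ord] * jac)
    de <- numeric(n); de[ord] <- jac
    gP[, c + 1L] <- gP[, c + 1L] + de * (1 - 2 * fg)
  }
  loss <- loss / length(classes)
  gP <- gP / length(classes)
  .ag_node(matrix(loss, 1L, 1L), list(probs), function(nd)
    .acc(nd$parents[[1]], gP * nd$grad[1L, 1L]))
}

#' Multiclass Lovasz-softmax loss
#'
#' For every class present in the labels, per-point errors
#' `e_i = 1 - p_i(c)` (if `y_i = c`) or `p_i(c)` otherwise are sorted in
#' decreasing order and dotted with the Jaccard-gradient vector of the sorted
#' ground truth; the class losses are averaged over the classes present.
#' Piecewise-linear convex surrogate of `1 - IoU`; lies in \[0, 1\].
#'
#' @param probs N x C matrix of softmax rows (or node).
#' @param labels integer labels; ignore-labeled points are dropped first.
#' @param ignore_label default -1.
#' @return scalar loss (numeric for matrix input, node for node input).
#' @export
lovasz_softmax <- function(probs, labels, ignore_label = -1L) {
  as_matrix <- !is.environment(probs)
  p <- .as_node(probs)
  valid <- which(labels != ignore_label)
  if (length(valid) == 0L) stop("no valid points for the Lovasz loss")
  out <- .ag_lovasz(ag_rows(p, valid), labels[valid])
  if (as_matrix) out$value[1L, 1L] else out
}

#' Composite loss: weighted CE plus Lovasz-softmax
#'
#' `L = alpha * L_CE + beta * L_Lovasz`. `beta = 0` reduces to the weighted
#' cross-entropy; `alpha = 0` to the Lovasz term alone.
#'
#' @param logits N x C matrix (or node).
#' @param labels integer labels in \{-1, 0, ..., C-1\}.
#' @param config a [loss_config()].
#' @return scalar loss (numeric for matrix input, node for node input).
#' @export
el_loss <- function(logits, labels, config = loss_config()) {
  as_matrix <- !is.environment(logits)
  lg <- .as_node(logits)
  total <- NULL
  if (config$alpha > 0) {
    ce <- weighted_cross_entropy(lg, labels, config$class_weights,
                                 config$ignore_label)
    total <- ag_smul(ce, config$alpha)
  }
  if (config$beta > 0) {
    valid <- which(labels != config$ignore_label)
    if (length(valid) == 0L) stop("all points carry the ignore label")
    probs <- ag_softmax_rows(ag_rows(lg, valid))
    lov <- ag_smul(.ag_lovasz(probs, labels[valid]), config$beta)
    total <- if (is.null(total)) lov else ag_add(total, lov)
  }
  if (as_matrix) total$value[1L, 1L] else total
}
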