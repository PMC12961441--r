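# The full segmentation network: a U-shaped point-transformer
# encoder-decoder over progressively grid-pooled point sets. Attention blocks
# are MRDCA (or a plain scaled dot-product KNN attention baseline when the
# toggle is off); the decoder output optionally passes through PG-InvFR
# before the linear segmentation head. Trained with the composite
# CE + Lovasz loss (or plain CE when toggled off) under AdamW and a
# multi-step learning-rate schedule.

#' Network configuration
#'
#' The backbone is a compact U-shape: per-stage channel widths, one attention
#' block per stage on both the encoder and decoder paths, and grid pooling
#' that doubles the cell size per stage (base cell 2 cm, scaled to seedling
#' dimensions). The three toggles switch the attention blocks
#' (`use_mrdca`), the pre-head refinement (`use_pg_invfr`) and the composite
#' loss (`use_el_loss`) independently, which spans the full ablation matrix.
#'
#' @param channels integer vector of per-stage widths (>= 2 stages),
#'   default `c(32, 64, 128, 256)` (the "desk" profile).
#' @param grid_base finest grid-pooling cell size in meters, default 0.02.
#' @param num_classes default 3 (leaf, stem, pot).
#' @param use_mrdca,use_pg_invfr,use_el_loss ablation toggles, default all on.
#' @param mrdca an [mrdca_config()].
#' @param pg a [pg_config()].
#' @param loss a [loss_config()] (used when `use_el_loss`; otherwise plain
#'   unweighted CE).
#' @param baseline_k neighbor count of the baseline attention, default 16.
#' @return a `ptv2fr_config` list.
#' @export
ptv2fr_config <- function(channels = c(32L, 64L, 128L, 256L), grid_base = 0.02,
                          num_classes = 3L, use_mrdca = TRUE,
                          use_pg_invfr = TRUE, use_el_loss = TRUE,
                          mrdca = mrdca_config(), pg = pg_config(),
                          loss = loss_config(), baseline_k = 16L) {
  if (length(channels) < 2L) stop("the backbone needs at least two stages")
  if (any(channels < 1L)) stop("channel widths must be positive")
  structure(list(channels = as.integer(channels), grid_base = grid_base,
                 num_classes = as.integer(num_classes),
                 use_mrdca = isTRUE(use_mrdca),
                 use_pg_invfr = isTRUE(use_pg_invfr),
                 use_el_loss = isTRUE(use_el_loss),
                 mrdca = mrdca, pg = pg, loss = loss,
                 baseline_k = as.integer(baseline_k)),
            class = "ptv2fr_config")
}

#' Training configuration
#'
#' Defaults follow the training protocol used throughout: AdamW with learning
#' rate 0.001 and weight decay 0.05, batch size 32, 100 epochs, and a
#' multi-step schedule multiplying the rate by 0.05 after epochs 60 and 80.
#'
#' @param batch_size clouds per optimizer step (gradient accumulation).
#' @param epochs training epochs.
#' @param lr base learning rate.
#' @param weight_decay decoupled AdamW weight decay.
#' @param milestones epochs after which the rate decays.
#' @param gamma decay factor at each milestone.
#' @param seed RNG seed for init and shuffling.
#' @param augment optional [augment_config()] applied to training clouds
#'   (`NULL` disables augmentation).
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 32L, epochs = 100L, lr = 0.001,
                         weight_decay = 0.05, milestones = c(60L, 80L),
                         gamma = 0.05, seed = 1L, augment = NULL) {
  milestones <- milestones[milestones < epochs]   # short runs drop late decays
  stopifnot(batch_size >= 1L, epochs >= 1L, lr > 0)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, weight_decay = weight_decay,
                 milestones = as.integer(milestones), gamma = gamma,
                 seed = as.integer(seed), augment = augment),
            class = "train_config")
}

#' Learning rate at a given epoch under the multi-step schedule
#' @param epoch 1-based epoch.
#' @param config a [train_config()].
#' @return the scheduled learning rate.
#' @export
scheduled_lr <- function(epoch, config) {
  config$lr * config$gamma^sum(epoch > config$milestones)
}

# ---- blocks ---------------------------------------------------------------

# baseline attention: scaled dot-product over one KNN graph (stands in for
# grouped vector attention when the MRDCA toggle is off)
.plain_attn_init <- function(d, K) {
  list(Wq = nn_linear(d, d), Wk = nn_linear(d, d), Wv = nn_linear(d, d, bias = FALSE),
       Wo = nn_lbr(d, d), K = K, d = d)
}

.plain_attn_forward <- function(params, f, coords, graph = NULL) {
  N <- nrow(ag_value(f)); K <- params$K
  if (is.null(graph)) graph <- build_knn_graph(coords, K)
  ctr <- rep(seq_len(N), each = K)
  nbr <- as.vector(t(graph$idx))
  q <- nn_linear_forward(params$Wq, f)
  k <- nn_linear_forward(params$Wk, f)
  v <- nn_linear_forward(params$Wv, f)
  s <- ag_smul(ag_rowsums(ag_mul(ag_rows(q, ctr), ag_rows(k, nbr))), 1 / sqrt(params$d))
  w <- ag_group_softmax(s, K)
  agg <- ag_rowsum_group(ag_rows_times_colvec(ag_rows(v, nbr), w), ctr, N)
  nn_lbr_forward(params$Wo, agg)
}

.block_init <- function(cfg, d) {
  if (cfg$use_mrdca) list(kind = "mrdca", mod = mrdca_init(d, d, cfg$mrdca))
  else list(kind = "plain", mod = .plain_attn_init(d, cfg$baseline_k))
}

.block_forward <- function(block, f, coords, graphs = NULL) {
  out <- if (block$kind == "mrdca") mrdca_forward(f, coords, block$mod, graphs)
         else .plain_attn_forward(block$mod, f, coords, graphs[[1L]])
  ag_add(f, out)   # residual
}

#' Build the segmentation model
#'
#' Assembles the U-shaped backbone for the given configuration: a feature
#' embedding of per-point color and centered coordinates, per-stage encoder
#' attention blocks with grid pooling between stages, decoder unpooling with
#' skip connections and attention blocks, optionally PG-InvFR, and the linear
#' head producing one logit per class.
#'
#' @param config a [ptv2fr_config()].
#' @param seed seed for parameter initialization.
#' @return a `ptv2fr_model` (parameter container + config).
#' @export
build_model <- function(config = ptv2fr_config(), seed = 1L) {
  set.seed(seed)
  ch <- config$channels
  S <- length(ch)
  enc <- dec <- down <- up <- vector("list", S)
  embed <- nn_lbr(6L, ch[1L])
  for (s in seq_len(S)) {
    enc[[s]] <- .block_init(config, ch[s])
    if (s < S) down[[s]] <- nn_lbr(ch[s], ch[s + 1L])
  }
  for (s in seq_len(S - 1L)) {
    up[[s]] <- nn_lbr(ch[s + 1L], ch[s])       # coarse -> fine width
    dec[[s]] <- .block_init(config, ch[s])
  }
  pg <- if (config$use_pg_invfr) pg_init(ch[1L], config$num_classes, config$pg) else NULL
  head <- nn_linear(ch[1L], config$num_classes)
  structure(list(embed = embed, enc = enc, down = down, up = up, dec = dec,
                 pg = pg, head = head, config = config, seed = seed),
            class = "ptv2fr_model")
}

#' Number of trainable scalar parameters
#' @param model a [build_model()] result.
#' @return integer parameter count (invariant to input size).
#' @export
n_parameters <- function(model) {
  sum(vapply(nn_params(model), function(p) length(p$value), integer(1)))
}

# Per-cloud geometry plan: coordinates, voxel-pooling groups and KNN graphs
# per stage, plus the PG-InvFR graph and geometric cues. Depends only on the
# coordinates, so training on static (unaugmented) clouds computes it once
# per cloud and reuses it every step.
.model_plan <- function(model, cloud) {
  cfg <- model$config
  S <- length(cfg$channels)
  ks <- if (cfg$use_mrdca) cfg$mrdca$k else cfg$baseline_k
  plan <- list(stages = vector("list", S))
  cc <- cloud$points
  grp_tab <- NULL
  for (s in seq_len(S)) {
    st <- list(coords = cc,
               graphs = lapply(ks, function(K) build_knn_graph(cc, K)))
    if (s < S) {
      cell <- cfg$grid_base * 2^(s - 1L)
      key <- floor(sweep(cc, 2L, apply(cc, 2L, min)) / cell)
      id <- paste(key[, 1L], key[, 2L], key[, 3L])
      uid <- sort(unique(id))
      st$grp <- match(id, uid)
      st$cnt <- tabulate(st$grp, nbins = length(uid))
      cc <- rowsum(cc, st$grp) / st$cnt
    }
    plan$stages[[s]] <- st
  }
  if (cfg$use_pg_invfr) {
    plan$pg_graph <- build_knn_graph(cloud$points, cfg$pg$k)
    plan$pg_geometry <- .pg_geometry(plan$pg_graph)
  }
  plan
}

# forward pass on one cloud; returns logits node plus auxiliary head output
.model_forward <- function(model, cloud, plan = NULL) {
  cfg <- model$config
  if (is.null(plan)) plan <- .model_plan(model, cloud)
  pts <- cloud$points
  feat0 <- cbind(cloud$colors / 255, sweep(pts, 2L, colMeans(pts)))
  f <- nn_lbr_forward(model$embed, ag_const(feat0))
  S <- length(cfg$channels)
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    st <- plan$stages[[s]]
    f <- .block_forward(model$enc[[s]], f, st$coords, st$graphs)
    skips[[s]] <- f
    if (s < S) {
      f <- ag_rows_times_colvec(ag_rowsum_group(f, st$grp, length(st$cnt)),
                                ag_const(matrix(1 / st$cnt, ncol = 1L)))
      f <- nn_lbr_forward(model$down[[s]], f)
    }
  }
  for (s in rev(seq_len(S - 1L))) {
    st <- plan$stages[[s]]
    f <- ag_rows(nn_lbr_forward(model$up[[s]], f), st$grp)  # unpool
    f <- ag_add(f, skips[[s]])
    f <- .block_forward(model$dec[[s]], f, st$coords, st$graphs)
  }
  aux <- NULL
  if (cfg$use_pg_invfr) {
    ref <- pg_invfr_forward(f, pts, model$pg, graph = plan$pg_graph,
                            geometry = plan$pg_geometry)
    f <- ref$features
    aux <- ref$aux_logits
  }
  list(logits = nn_linear_forward(model$head, f), aux = aux)
}

# training loss for one cloud under the configured toggles
.model_loss <- function(model, cloud, plan = NULL) {
  cfg <- model$config
  fw <- .model_forward(model, cloud, plan)
  lcfg <- if (cfg$use_el_loss) cfg$loss else loss_config(alpha = 1, beta = 0)
  loss <- el_loss(fw$logits, cloud$labels, lcfg)
  if (!is.null(fw$aux) && cfg$pg$aux_head_weight > 0) {
    auxl <- weighted_cross_entropy(fw$aux, cloud$labels, lcfg$class_weights)
    loss <- ag_add(loss, ag_smul(auxl, cfg$pg$aux_head_weight))
  }
  loss
}

#' Train the segmentation model
#'
#' Epoch loop over the training clouds with gradient accumulation to the
#' configured batch size, AdamW updates under the multi-step schedule, and
#' (when a validation set is given) per-epoch macro-IoU tracking with
#' best-checkpoint selection. Class weights for the composite loss are
#' computed once from the training labels when the config requests `NULL`
#' weights.
#'
#' @param model a [build_model()] result (updated in place and returned).
#' @param train_clouds list of labeled clouds.
#' @param config a [train_config()].
#' @param val_clouds optional validation clouds.
#' @param verbose print per-epoch progress.
#' @return a list with the trained `model`, `log` (data.frame of per-epoch
#'   loss/lr/val mIoU), and `best` (epoch and val mIoU of the kept weights).
#' @export
train <- function(model, train_clouds, config = train_config(),
                  val_clouds = NULL, verbose = FALSE) {
  if (length(train_clouds) == 0L) stop("empty training split")
  set.seed(config$seed)
  cfg <- model$config
  if (cfg$use_el_loss && is.null(cfg$loss$class_weights)) {
    cfg$loss$class_weights <- class_weights_from_frequency(
      lapply(train_clouds, `[[`, "labels"), cfg$num_classes)
    model$config <- cfg
  }
  params <- nn_params(model)
  # static clouds: compute the per-cloud geometry plan once and reuse it
  plans <- if (is.null(config$augment))
    lapply(train_clouds, function(cl) .model_plan(model, cl)) else NULL
  log <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                    val_miou = numeric())
  best <- list(epoch = NA_integer_, val_miou = -Inf, values = NULL)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- scheduled_lr(epoch, config)
    ord <- sample(length(train_clouds))
    ep_loss <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      take <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      i <- i + length(take)
      ag_begin()
      batch_loss <- 0
      for (ci in take) {
        cl <- train_clouds[[ci]]
        if (!is.null(config$augment)) cl <- augment(cl, config$augment)
        loss <- .model_loss(model, cl, if (is.null(plans)) NULL else plans[[ci]])
        ag_backward(loss)
        batch_loss <- batch_loss + loss$value[1L, 1L]
        ag_begin()
      }
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / length(take)
      step <- step + 1L
      adamw_step(params, lr, step, weight_decay = config$weight_decay)
      ep_loss <- ep_loss + batch_loss / length(take)
      nb <- nb + 1L
    }
    vm <- NA_real_
    if (!is.null(val_clouds)) {
      pred <- unlist(lapply(val_clouds, function(cl) predict_cloud(model, cl)$labels))
      truth <- unlist(lapply(val_clouds, `[[`, "labels"))
      vm <- mean_iou(evaluate_labels(pred, truth, cfg$num_classes))
      if (vm > best$val_miou) {
        best <- list(epoch = epoch, val_miou = vm,
                     values = lapply(params, function(p) p$value))
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = ep_loss / nb, lr = lr,
                                 val_miou = vm))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.5f  val mIoU %s",
                      epoch, ep_loss / nb, lr,
                      if (is.na(vm)) "-" else sprintf("%.3f", vm)))
  }
  if (!is.null(best$values)) {
    for (j in seq_along(params)) params[[j]]$value <- best$values[[j]]
    best$values <- NULL
  }
  list(model = model, log = log, best = best)
}

#' Run one optimization step count on a fixed set of clouds
#'
#' Lightweight alternative to [train()] for overfit sanity checks: `steps`
#' single-cloud updates cycling through `clouds` at a fixed learning rate.
#'
#' @param model a model; updated in place.
#' @param clouds list of clouds.
#' @param steps number of optimizer steps.
#' @param lr learning rate.
#' @param weight_decay AdamW weight decay.
#' @param seed shuffle seed.
#' @return the final mean training loss over the last cycle, invisibly.
#' @export
train_steps <- function(model, clouds, steps, lr = 0.005, weight_decay = 0.01,
                        seed = 1L) {
  set.seed(seed)
  cfg <- model$config
  if (cfg$use_el_loss && is.null(cfg$loss$class_weights)) {
    model$config$loss$class_weights <- class_weights_from_frequency(
      lapply(clouds, `[[`, "labels"), cfg$num_classes)
  }
  params <- nn_params(model)
  plans <- lapply(clouds, function(cl) .model_plan(model, cl))
  last <- NA_real_
  for (s in seq_len(steps)) {
    ci <- (s - 1L) %% length(clouds) + 1L
    cl <- clouds[[ci]]
    ag_begin()
    loss <- .model_loss(model, cl, plans[[ci]])
    ag_backward(loss)
    last <- loss$value[1L, 1L]
    adamw_step(params, lr, s, weight_decay = weight_decay)
    ag_begin()
  }
  invisible(last)
}

#' Segment a cloud with a trained model
#'
#' Full-cloud inference. Clouds above `max_points` are processed as a union
#' of sphere crops (each crop labels its so-far-unlabeled members around an
#' unlabeled center) so every point is labeled exactly once.
#'
#' @param model a trained model.
#' @param cloud a [labeled_cloud()] (its labels are ignored).
#' @param max_points largest cloud processed in one pass, default 20000.
#' @return a `segmentation_output`: list with `logits` (N x C),
#'   `probabilities` (rows sum to 1), and hard `labels` (0-based argmax).
#' @export
predict_cloud <- function(model, cloud, max_points = 20000L) {
  N <- n_points(cloud)
  if (N <= max_points) {
    logits <- ag_value(.model_forward(model, cloud)$logits)
  } else {
    logits <- matrix(NA_real_, N, model$config$num_classes)
    while (anyNA(logits[, 1L])) {
      todo <- which(is.na(logits[, 1L]))
      ctr <- todo[1L]
      d2 <- rowSums(sweep(cloud$points, 2L, cloud$points[ctr, ])^2)
      crop <- order(d2)[seq_len(min(max_points, N))]
      lg <- ag_value(.model_forward(model, cloud_subset(cloud, crop))$logits)
      fill <- crop %in% todo
      logits[crop[fill], ] <- lg[fill, , drop = FALSE]
    }
  }
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  structure(list(logits = logits, probabilities = probs,
                 labels = max.col(logits, ties.method = "first") - 1L),
            class = "segmentation_output")
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the configuration echo, seed and all parameter
#' values.
#'
#' @param model a model.
#' @param path checkpoint path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  params <- nn_params(model)
  saveRDS(list(config = model$config, seed = model$seed,
               values = lapply(params, function(p) p$value)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = ck$seed)
  params <- nn_params(model)
  if (length(params) != length(ck$values))
    stop("checkpoint does not match the rebuilt model")
  for (j in seq_along(params)) params[[j]]$value <- ck$values[[j]]
  model
}
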