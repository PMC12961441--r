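# Furthest-point sampling, pot-level dataset splitting, and the training-time
# augmentations (random scale / flip / jitter / elastic distortion / sphere
# crop).

#' Furthest-point-sample a cloud
#'
#' Greedy max-min subsampling: starting from a seed point, each subsequent
#' pick is the point maximizing the minimum distance to the already-selected
#' set. Preserves spatial coverage far better than uniform random sampling;
#' clouds are downsampled to 4096 points before training by default.
#'
#' Determinism: the start point is the first element of a seeded shuffle of
#' the indices (segmentation results depend only weakly on the start point);
#' distance ties are resolved toward the lowest point index. An explicit
#' `start` index overrides the seeded choice.
#'
#' @param cloud a [labeled_cloud()].
#' @param m target number of points (>= 1). Clouds with at most `m` points
#'   are returned unchanged.
#' @param seed integer seed for the start-point shuffle.
#' @param start optional 1-based index of the first selected point.
#' @return the subsampled cloud; labels and colors are carried along.
#' @export
fps_downsample <- function(cloud, m = 4096L, seed = 1L, start = NULL) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer")
  n <- n_points(cloud)
  if (n <= m) return(cloud)
  if (is.null(start)) {
    set.seed(seed)
    start <- sample.int(n, 1L)
  }
  idx <- cpp_fps(cloud$points, m, as.integer(start))
  cloud_subset(cloud, idx)
}

#' Furthest-point-sampling indices
#'
#' Lower-level access to the greedy max-min selection used by
#' [fps_downsample()]; returns indices instead of a cloud.
#'
#' @param points numeric N x 3 matrix.
#' @param m number of points to select.
#' @param start 1-based index of the first selected point.
#' @return integer vector of `m` selected indices.
#' @export
fps_indices <- function(points, m, start = 1L) {
  if (m < 1L || m > nrow(points)) stop("`m` must be in [1, N]")
  cpp_fps(as.matrix(points), as.integer(m), as.integer(start))
}

#' Split a dataset at the pot level
#'
#' Partitions distinct pot ids into train/validation/test subsets so that all
#' clouds sharing a pot id (every timepoint of one physical pot) fall in the
#' same subset, preventing temporal leakage. Subset sizes follow the ratio
#' with validation and test floored and the remainder assigned to train
#' (50 pots at 7:2:1 gives 35/10/5).
#'
#' @param pot_ids character vector of pot ids (one entry per cloud is fine;
#'   duplicates collapse to distinct pots).
#' @param ratio numeric length-3 train/val/test ratio, default `c(7, 2, 1)`.
#' @param seed integer seed controlling the shuffle.
#' @return a `pot_split`: list with `assignment` (named character vector
#'   pot -> subset), `ratio`, and `seed`.
#' @export
pot_level_split <- function(pot_ids, ratio = c(7, 2, 1), seed = 1L) {
  pots <- unique(as.character(pot_ids))
  if (length(pots) < 3L) stop("need at least 3 distinct pots to split")
  if (length(ratio) != 3L || any(ratio < 0) || sum(ratio) <= 0)
    stop("`ratio` must be three non-negative numbers")
  frac <- ratio / sum(ratio)
  n <- length(pots)
  n_val <- floor(n * frac[2])
  n_test <- floor(n * frac[3])
  n_train <- n - n_val - n_test
  set.seed(seed)
  shuffled <- sample(pots)
  subset <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  assignment <- stats::setNames(subset, shuffled)[pots]
  structure(list(assignment = assignment, ratio = ratio, seed = seed),
            class = "pot_split")
}

#' Augmentation configuration
#'
#' Training-time augmentation parameters: a single per-cloud scale factor in
#' `scale_range`, independent x/y flips with probability `flip_prob` (never
#' z; seedlings are gravity-oriented), per-point Gaussian jitter with
#' `jitter_sigma` clipped at `jitter_clip`, elastic distortion with
#' (granularity, magnitude) pairs, and a sphere crop capping the point count.
#'
#' @param scale_range length-2 numeric, default `c(0.9, 1.1)`.
#' @param flip_prob flip probability per horizontal axis, default 0.5.
#' @param jitter_sigma Gaussian jitter s.d. (meters), default 0.005.
#' @param jitter_clip absolute per-coordinate jitter bound, default 0.02.
#' @param elastic_params list of (granularity, magnitude) pairs, default
#'   `list(c(0.2, 0.4), c(0.8, 1.6))`.
#' @param sphere_crop_max maximum surviving points, default 80000.
#' @return an `augment_config` list.
#' @export
augment_config <- function(scale_range = c(0.9, 1.1), flip_prob = 0.5,
                           jitter_sigma = 0.005, jitter_clip = 0.02,
                           elastic_params = list(c(0.2, 0.4), c(0.8, 1.6)),
                           sphere_crop_max = 80000L) {
  stopifnot(length(scale_range) == 2L, all(scale_range > 0),
            flip_prob >= 0, flip_prob <= 1,
            jitter_sigma >= 0, jitter_clip >= 0, sphere_crop_max >= 1L)
  structure(list(scale_range = scale_range, flip_prob = flip_prob,
                 jitter_sigma = jitter_sigma, jitter_clip = jitter_clip,
                 elastic_params = elastic_params,
                 sphere_crop_max = as.integer(sphere_crop_max)),
            class = "augment_config")
}

# One smoothed random displacement field: Gaussian-blurred noise on a coarse
# grid at spacing `granularity`, trilinearly interpolated at the points and
# scaled by `magnitude`.
.elastic_field <- function(points, granularity, magnitude) {
  lo <- apply(points, 2, min); hi <- apply(points, 2, max)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / granularity)) + 3L)
  disp <- array(stats::rnorm(prod(dims) * 3L), dim = c(dims, 3L))
  # separable 3-tap blur along each spatial axis, two passes
  smooth_axis <- function(a, d) {
    n <- dim(a)[d]
    if (n < 2L) return(a)
    shift <- function(a, k) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)
      switch(d,
             a[idx, , , , drop = FALSE],
             a[, idx, , , drop = FALSE],
             a[, , idx, , drop = FALSE])
    }
    (shift(a, -1L) + 2 * a + shift(a, 1L)) / 4
  }
  for (pass in 1:2) for (d in 1:3) disp <- smooth_axis(disp, d)
  # trilinear interpolation of the field at the points
  g <- sweep(points, 2, lo) / granularity + 1  # grid coords, 1-based
  g0 <- floor(g)
  for (c in 1:3) g0[, c] <- pmin(pmax(g0[, c], 1), dims[c] - 1L)
  frac <- g - g0
  out <- matrix(0, nrow(points), 3L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (ifelse(dx == 1, frac[, 1], 1 - frac[, 1]) *
          ifelse(dy == 1, frac[, 2], 1 - frac[, 2]) *
          ifelse(dz == 1, frac[, 3], 1 - frac[, 3]))
    ix <- pmin(g0[, 1] + dx, dim(disp)[1])
    iy <- pmin(g0[, 2] + dy, dim(disp)[2])
    iz <- pmin(g0[, 3] + dz, dim(disp)[3])
    for (c in 1:3)
      out[, c] <- out[, c] + w * disp[cbind(ix, iy, iz, c)]
  }
  out * magnitude * granularity
}

#' Apply training augmentations to a cloud
#'
#' Applies, in order: random per-cloud scaling, random horizontal flips,
#' elastic distortion, Gaussian jitter (clipped), and a sphere crop centered
#' on a random retained point when the cloud exceeds the crop limit. Labels
#' and colors of surviving points are unchanged. Uses the current R RNG
#' state; seed with `set.seed()` for reproducibility.
#'
#' @param cloud a [labeled_cloud()].
#' @param config an [augment_config()].
#' @return the augmented cloud.
#' @export
augment <- function(cloud, config = augment_config()) {
  pts <- cloud$points
  s <- stats::runif(1, config$scale_range[1], config$scale_range[2])
  pts <- pts * s
  for (ax in 1:2) if (stats::runif(1) < config$flip_prob) pts[, ax] <- -pts[, ax]
  for (pair in config$elastic_params)
    pts <- pts + .elastic_field(pts, pair[1], pair[2])
  if (config$jitter_sigma > 0) {
    j <- matrix(stats::rnorm(length(pts), 0, config$jitter_sigma), ncol = 3L)
    j <- pmin(pmax(j, -config$jitter_clip), config$jitter_clip)
    pts <- pts + j
  }
  cloud$points <- pts
  if (n_points(cloud) > config$sphere_crop_max) {
    center <- sample.int(n_points(cloud), 1L)
    d2 <- rowSums(sweep(cloud$points, 2, cloud$points[center, ])^2)
    keep <- order(d2)[seq_len(config$sphere_crop_max)]
    cloud <- cloud_subset(cloud, sort(keep))
  }
  cloud
}
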