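# Phenotypic trait extraction from a semantically segmented cloud:
# stem instancing by DBSCAN on the xy projection, per-stem axis by RANSAC
# line consensus refined with PCA, leaf-to-plant assignment by nearest stem
# centroid, per-plant leaf instancing by 3-D DBSCAN, leaf length/width from
# PCA extents, leaf area by Delaunay triangulation of the PCA-plane
# projection with 3-D triangle areas, stem length/diameter conventions, and
# the pot-level summary (leaf count, LAI, mean stem height/diameter).
#
# Coordinates are meters throughout; trait records report lengths and areas
# in cm/cm2 and stem diameter in mm.

#' Stem clustering configuration
#'
#' @param eps DBSCAN radius in meters on the xy projection, default 0.03
#'   (3 cm, the default stem interval).
#' @param min_pts DBSCAN core threshold, default 80.
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(eps = 0.03, min_pts = 80L) {
  stopifnot(eps > 0, min_pts >= 1L)
  structure(list(eps = eps, min_pts = as.integer(min_pts)),
            class = "cluster_config")
}

#' RANSAC line-fit configuration
#'
#' @param tau inlier distance threshold in meters, default 0.01.
#' @param iterations number of 2-point hypotheses, default 120.
#' @param seed RNG seed for the draws.
#' @return a `ransac_config` list.
#' @export
ransac_config <- function(tau = 0.01, iterations = 120L, seed = 1L) {
  stopifnot(tau > 0, iterations >= 1L)
  structure(list(tau = tau, iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "ransac_config")
}

#' Split a labeled cloud by semantic class
#'
#' @param cloud a [labeled_cloud()] with labels.
#' @return list of coordinate matrices `stem`, `leaf`, `pot` (ignore-labeled
#'   points appear in none). Warns when no stem points are present.
#' @export
split_by_label <- function(cloud) {
  out <- list(leaf = cloud$points[cloud$labels == 0L, , drop = FALSE],
              stem = cloud$points[cloud$labels == 1L, , drop = FALSE],
              pot = cloud$points[cloud$labels == 2L, , drop = FALSE])
  if (nrow(out$stem) == 0L)
    warning("cloud contains no stem points; trait record will be empty")
  out
}

#' Cluster stem points into plant instances
#'
#' DBSCAN with (`eps`, `min_pts`) on the xy projection of the stem points;
#' noise points are discarded. Each cluster becomes a partial plant instance
#' carrying its stem points and xy centroid.
#'
#' @param stem_points matrix of stem coordinates (meters).
#' @param config a [cluster_config()].
#' @return list of `plant_instance` lists (`id`, `points`, `centroid`).
#' @export
cluster_stems <- function(stem_points, config = cluster_config()) {
  if (nrow(stem_points) == 0L) return(list())
  lab <- cpp_dbscan(stem_points[, 1:2, drop = FALSE], config$eps, config$min_pts)
  ids <- sort(unique(lab[lab > 0L]))
  lapply(seq_along(ids), function(i) {
    pts <- stem_points[lab == ids[i], , drop = FALSE]
    structure(list(id = i, points = pts, centroid = colMeans(pts[, 1:2, drop = FALSE])),
              class = "plant_instance")
  })
}

# perpendicular distances from points to the line through p0 with unit
# direction vhat
.line_dist <- function(x, p0, vhat) {
  d <- sweep(x, 2L, p0)
  cx <- cbind(d[, 2L] * vhat[3L] - d[, 3L] * vhat[2L],
              d[, 3L] * vhat[1L] - d[, 1L] * vhat[3L],
              d[, 1L] * vhat[2L] - d[, 2L] * vhat[1L])
  sqrt(rowSums(cx^2))
}

#' Fit the stem axis of a plant instance
#'
#' RANSAC line consensus (2-point hypotheses, `iterations` draws, inlier
#' threshold `tau`; the model with the largest inlier count wins, earliest
#' iteration on ties) followed by PCA refinement: SVD of the centered inlier
#' set, first principal component as the axis, sign fixed to a non-negative
#' z component, anchored at the inlier mean.
#'
#' @param plant a `plant_instance` from [cluster_stems()].
#' @param config a [ransac_config()].
#' @return the plant with `axis` (unit 3-vector, `axis[3] >= 0`), `anchor`
#'   (inlier mean) and `inliers` (logical over its points) filled in.
#' @export
fit_stem_axis <- function(plant, config = ransac_config()) {
  pts <- plant$points
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 stem points to fit an axis")
  if (all(apply(pts, 2L, function(c) diff(range(c))) < 1e-12))
    stop("degenerate stem: all points coincident")
  set.seed(config$seed)
  best_cnt <- -1L
  best_in <- NULL
  for (it in seq_len(config$iterations)) {
    pick <- sample.int(n, 2L)
    v <- pts[pick[2L], ] - pts[pick[1L], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    d <- .line_dist(pts, pts[pick[1L], ], v / nv)
    inl <- d <= config$tau
    if (sum(inl) > best_cnt) { best_cnt <- sum(inl); best_in <- inl }
  }
  if (is.null(best_in) || sum(best_in) < 2L) best_in <- rep(TRUE, n)
  inpts <- pts[best_in, , drop = FALSE]
  ctr <- colMeans(inpts)
  sv <- svd(sweep(inpts, 2L, ctr))
  a <- sv$v[, 1L]
  if (a[3L] < 0) a <- -a
  plant$axis <- a
  plant$anchor <- ctr
  plant$inliers <- best_in
  plant
}

#' Assign leaf points to plants by nearest stem centroid
#'
#' Each leaf point goes to the plant whose stem cluster centroid is closest
#' in the xy plane (ties to the lower plant id), so per-plant leaf
#' processing cannot interfere across plants.
#'
#' @param leaf_points matrix of leaf coordinates.
#' @param plants list of plant instances.
#' @return integer vector assigning each leaf point to a plant id, or an
#'   all-`NA` vector when there are no plants.
#' @export
assign_leaves <- function(leaf_points, plants) {
  if (nrow(leaf_points) == 0L) return(integer(0))
  if (length(plants) == 0L) {
    warning("no plants; leaf points left unassigned")
    return(rep(NA_integer_, nrow(leaf_points)))
  }
  cen <- do.call(rbind, lapply(plants, `[[`, "centroid"))
  d2 <- outer(leaf_points[, 1L], cen[, 1L], `-`)^2 +
        outer(leaf_points[, 2L], cen[, 2L], `-`)^2
  apply(d2, 1L, which.min)   # which.min ties -> lowest plant id
}

#' Segment one plant's leaf points into leaf instances
#'
#' 3-D DBSCAN separates the leaves of a plant; noise is dropped. Leaves that
#' touch within `eps` merge into one instance (documented limitation).
#'
#' @param plant_leaf_points matrix of one plant's leaf coordinates.
#' @param eps DBSCAN radius in meters, default 0.01.
#' @param min_pts core threshold, default 20.
#' @return list of coordinate matrices, one per leaf instance.
#' @export
segment_leaves <- function(plant_leaf_points, eps = 0.01, min_pts = 20L) {
  if (nrow(plant_leaf_points) == 0L) return(list())
  lab <- cpp_dbscan(plant_leaf_points, eps, as.integer(min_pts))
  ids <- sort(unique(lab[lab > 0L]))
  lapply(ids, function(i) plant_leaf_points[lab == i, , drop = FALSE])
}

#' Leaf length and width from PCA extents
#'
#' PCA on the centered leaf points; length is the extent (max minus min
#' projection) along the first principal axis, width along the second, so
#' `L >= W` on planar leaves. A `use_third_component` flag measures the
#' width along the third axis instead.
#'
#' @param leaf matrix of leaf coordinates (meters), at least 3 non-collinear
#'   points.
#' @param use_third_component measure width along PC3 instead of PC2.
#' @return list with `length_cm`, `width_cm`, the axes `u1`, `u2`, and the
#'   projections `pi1`, `pi2`.
#' @export
leaf_dimensions <- function(leaf, use_third_component = FALSE) {
  if (nrow(leaf) < 3L) stop("need at least 3 points for leaf dimensions")
  ctr <- colMeans(leaf)
  x <- sweep(leaf, 2L, ctr)
  sv <- svd(x)
  u1 <- sv$v[, 1L]
  u2 <- sv$v[, if (use_third_component) 3L else 2L]
  p1 <- x %*% u1
  p2 <- x %*% u2
  list(length_cm = (max(p1) - min(p1)) * 100,
       width_cm = (max(p2) - min(p2)) * 100,
       u1 = u1, u2 = u2, pi1 = as.vector(p1), pi2 = as.vector(p2))
}

#' Leaf surface area by Delaunay triangulation
#'
#' Triangulates the leaf points projected onto their first two principal
#' axes and sums the 3-D areas `0.5 * |(p_j - p_i) x (p_k - p_i)|` of the
#' triangles evaluated at the original coordinates. Robust to slight
#' wrinkling; collinear input yields area 0 with a warning.
#'
#' Boundary slivers — triangles whose longest projected edge far exceeds the
#' typical triangle edge — chord across the curved leaf margin and would add
#' spurious off-surface area, so triangles with a longest edge above
#' `edge_factor` times the median longest edge are dropped (an alpha-shape
#' style filter; it never triggers on single triangles or uniform grids).
#'
#' @param leaf matrix of leaf coordinates (meters).
#' @param to_cm2 convert from m2 to cm2 (default TRUE).
#' @param edge_factor sliver-filter multiplier, default 5.
#' @return scalar area.
#' @export
leaf_area <- function(leaf, to_cm2 = TRUE, edge_factor = 5) {
  if (nrow(leaf) < 3L) stop("need at least 3 points for leaf area")
  dims <- leaf_dimensions(leaf)
  tri <- cpp_delaunay(dims$pi1, dims$pi2)
  if (nrow(tri) == 0L) {
    warning("leaf points are collinear; area is 0")
    return(0)
  }
  p2 <- cbind(dims$pi1, dims$pi2)
  elen <- function(i, j) sqrt(rowSums((p2[tri[, i], , drop = FALSE] -
                                       p2[tri[, j], , drop = FALSE])^2))
  emax <- pmax(elen(1L, 2L), elen(2L, 3L), elen(1L, 3L))
  keep <- emax <= edge_factor * stats::median(emax)
  if (any(keep)) tri <- tri[keep, , drop = FALSE]
  a <- leaf[tri[, 1L], , drop = FALSE]
  b <- leaf[tri[, 2L], , drop = FALSE]
  c <- leaf[tri[, 3L], , drop = FALSE]
  ab <- b - a; ac <- c - a
  cx <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
              ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
              ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  area <- 0.5 * sum(sqrt(rowSums(cx^2)))
  if (to_cm2) area * 1e4 else area
}

#' Stem length and diameter of a fitted plant
#'
#' Stem length is the extent of the stem points projected onto the fitted
#' axis (cm). Stem diameter is twice the median perpendicular distance to
#' the axis among points in the basal 20% of the axial extent (mm) — a
#' robust basal-diameter convention.
#'
#' @param plant a plant with a fitted axis ([fit_stem_axis()]).
#' @return list with `stem_length_cm` and `stem_diameter_mm`.
#' @export
stem_traits <- function(plant) {
  if (is.null(plant$axis)) stop("fit the stem axis first")
  pts <- plant$points
  if (nrow(pts) < 2L) stop("need at least 2 stem points")
  t <- as.vector(sweep(pts, 2L, plant$anchor) %*% plant$axis)
  len <- max(t) - min(t)
  basal <- t <= min(t) + 0.2 * len
  d <- .line_dist(pts[basal, , drop = FALSE], plant$anchor, plant$axis)
  list(stem_length_cm = len * 100,
       stem_diameter_mm = 2 * stats::median(d) * 1000)
}

#' Pot-level trait summary
#'
#' Leaf count, leaf area index (total leaf area divided by the 625 cm2 tray
#' footprint), and mean stem height/diameter over the plants.
#'
#' @param records a `trait_record` from [extract_traits()] (or a compatible
#'   list with `leaves` and `plants` data.frames).
#' @param unit_area_cm2 LAI normalizer, default 625 (25 cm x 25 cm tray).
#' @return list with `leaf_count`, `lai`, `mean_stem_height_cm`,
#'   `mean_stem_diameter_mm`.
#' @export
pot_summary <- function(records, unit_area_cm2 = 625) {
  leaves <- records$leaves
  plants <- records$plants
  list(leaf_count = if (is.null(leaves)) 0L else nrow(leaves),
       lai = if (is.null(leaves) || nrow(leaves) == 0L) 0
             else sum(leaves$area_cm2) / unit_area_cm2,
       mean_stem_height_cm = if (is.null(plants) || nrow(plants) == 0L) NA_real_
                             else mean(plants$stem_length_cm),
       mean_stem_diameter_mm = if (is.null(plants) || nrow(plants) == 0L) NA_real_
                               else mean(plants$stem_diameter_mm))
}

#' End-to-end trait extraction from a segmented cloud
#'
#' Runs the full pipeline: optional rescale to meters, class split, stem
#' DBSCAN, per-plant RANSAC+PCA axes, leaf assignment and instancing, leaf
#' dimensions and Delaunay areas, and the pot summary.
#'
#' @param cloud a segmented [labeled_cloud()].
#' @param scale uniform factor applied first ([rescale_cloud()]), default 1.
#' @param cluster a [cluster_config()].
#' @param ransac a [ransac_config()].
#' @param leaf_eps,leaf_min_pts leaf-instancing DBSCAN parameters.
#' @return a `trait_record`: list with data.frames `plants` (id, centroid,
#'   axis, stem length cm, stem diameter mm), `leaves` (plant id, leaf id,
#'   length/width cm, area cm2, point count) and the `pot` summary.
#' @export
extract_traits <- function(cloud, scale = 1, cluster = cluster_config(),
                           ransac = ransac_config(), leaf_eps = 0.008,
                           leaf_min_pts = 20L) {
  cloud <- rescale_cloud(cloud, scale)
  parts <- split_by_label(cloud)
  plants <- cluster_stems(parts$stem, cluster)
  if (length(plants) == 0L) {
    rec <- structure(list(plants = NULL, leaves = NULL), class = "trait_record")
    rec$pot <- pot_summary(rec)
    return(rec)
  }
  plants <- lapply(plants, fit_stem_axis, config = ransac)
  pdf <- do.call(rbind, lapply(plants, function(p) {
    st <- stem_traits(p)
    data.frame(plant = p$id, centroid_x = p$centroid[1L],
               centroid_y = p$centroid[2L],
               axis_x = p$axis[1L], axis_y = p$axis[2L], axis_z = p$axis[3L],
               n_stem_points = nrow(p$points),
               stem_length_cm = st$stem_length_cm,
               stem_diameter_mm = st$stem_diameter_mm)
  }))
  ldf <- NULL
  if (nrow(parts$leaf) > 0L) {
    owner <- assign_leaves(parts$leaf, plants)
    rows <- list()
    for (p in seq_along(plants)) {
      lp <- parts$leaf[which(owner == p), , drop = FALSE]
      if (nrow(lp) == 0L) next
      insts <- segment_leaves(lp, eps = leaf_eps, min_pts = leaf_min_pts)
      for (k in seq_along(insts)) {
        if (nrow(insts[[k]]) < 3L) next
        dims <- leaf_dimensions(insts[[k]])
        rows[[length(rows) + 1L]] <- data.frame(
          plant = p, leaf = k, n_points = nrow(insts[[k]]),
          length_cm = dims$length_cm, width_cm = dims$width_cm,
          area_cm2 = leaf_area(insts[[k]]))
      }
    }
    if (length(rows) > 0L) ldf <- do.call(rbind, rows)
  }
  rec <- structure(list(plants = pdf, leaves = ldf), class = "trait_record")
  rec$pot <- pot_summary(rec)
  rec
}

#' Write a trait record to CSV
#'
#' One row per leaf (`row_type = "leaf"`) and per plant (`"plant"`) plus a
#' pot-summary row (`"pot"`), with a fixed documented column set.
#'
#' @param record a `trait_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(record, path) {
  cols <- c("row_type", "plant", "leaf", "stem_length_cm", "stem_diameter_mm",
            "length_cm", "width_cm", "area_cm2", "leaf_count", "lai",
            "mean_stem_height_cm", "mean_stem_diameter_mm")
  blank <- function(n) data.frame(matrix(NA, n, length(cols),
                                         dimnames = list(NULL, cols)))
  out <- list()
  if (!is.null(record$plants)) {
    b <- blank(nrow(record$plants))
    b$row_type <- "plant"; b$plant <- record$plants$plant
    b$stem_length_cm <- record$plants$stem_length_cm
    b$stem_diameter_mm <- record$plants$stem_diameter_mm
    out[[length(out) + 1L]] <- b
  }
  if (!is.null(record$leaves)) {
    b <- blank(nrow(record$leaves))
    b$row_type <- "leaf"; b$plant <- record$leaves$plant
    b$leaf <- record$leaves$leaf
    b$length_cm <- record$leaves$length_cm
    b$width_cm <- record$leaves$width_cm
    b$area_cm2 <- record$leaves$area_cm2
    out[[length(out) + 1L]] <- b
  }
  b <- blank(1L)
  b$row_type <- "pot"
  b$leaf_count <- record$pot$leaf_count
  b$lai <- record$pot$lai
  b$mean_stem_height_cm <- record$pot$mean_stem_height_cm
  b$mean_stem_diameter_mm <- record$pot$mean_stem_diameter_mm
  out[[length(out) + 1L]] <- b
  utils::write.csv(do.call(rbind, out), path, row.names = FALSE)
  invisible(path)
}
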