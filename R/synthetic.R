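# Procedural generator of labeled sorghum-seedling pot clouds with
# analytically known traits. One tray (25 x 25 x 5 cm) carries 15-25
# seedlings on a jittered 5 x 5 grid; each seedling is a thin, slightly
# curved stem (sampled on a cylinder surface) with 2-3 leaves modeled as
# constant-curvature cylinder-section ribbons, so chord length, width and
# surface area have closed forms. Clouds exhibit the hallmarks of multi-view
# reconstruction: Gaussian surface noise, density decreasing with height and
# random occlusion sectors with thinned sampling, and severe class imbalance
# (stems are a small minority of points).

#' Pot specification
#'
#' Defaults encode the study conditions the generator emulates: a 25 cm
#' square tray, 15-25 seedlings per pot, stem heights around 4 cm with
#' millimeter-scale radii, and leaves a few cm long.
#'
#' @param n_plants number of seedlings; `NULL` draws uniformly from 15-25.
#' @param grid_jitter s.d. of the grid-position jitter in meters, default 1 mm.
#' @param tray tray dimensions (x, y, z) in meters, default 0.25 x 0.25 x 0.05.
#' @param stem_length_range stem length range in meters, default 3-5 cm.
#' @param stem_radius_range stem radius range in meters, default 1-1.5 mm.
#' @param stem_curvature relative tip offset of the stem centerline, default
#'   0.05 (5% of length); 0 gives perfectly straight stems.
#' @param leaves_per_plant integer range, default 2-3.
#' @param leaf_arc_range leaf arc length range in meters, default 2.5-4.5 cm.
#' @param leaf_width_range leaf width range in meters, default 0.6-1.2 cm.
#' @param leaf_bend_angle_range total bend of the leaf arc in radians,
#'   default 0.4-1.0.
#' @param points_per_stem,points_per_leaf,tray_points sampling budget per
#'   structure before thinning.
#' @param noise_sigma Gaussian surface noise s.d. in meters, default 0.3 mm;
#'   0 gives noise-free clouds.
#' @param wrinkle_amp amplitude (meters) of a sinusoidal normal perturbation
#'   on leaves, default 0 (flat ribbons).
#' @param density_gradient fraction of thinning at the cloud top, default 0.3.
#' @param occlusion_sectors number of random thinned angular sectors,
#'   default 1.
#' @param density_scale multiplier on all point budgets, default 1.
#' @return a `pot_spec` list.
#' @export
pot_spec <- function(n_plants = NULL, grid_jitter = 0.001,
                     tray = c(0.25, 0.25, 0.05),
                     stem_length_range = c(0.03, 0.05),
                     stem_radius_range = c(0.001, 0.0015),
                     stem_curvature = 0.05,
                     leaves_per_plant = c(2L, 3L),
                     leaf_arc_range = c(0.025, 0.045),
                     leaf_width_range = c(0.006, 0.012),
                     leaf_bend_angle_range = c(0.4, 1.0),
                     points_per_stem = 80L, points_per_leaf = 200L,
                     tray_points = 6000L, noise_sigma = 3e-4,
                     wrinkle_amp = 0, density_gradient = 0.3,
                     occlusion_sectors = 1L, density_scale = 1) {
  structure(as.list(environment()), class = "pot_spec")
}

# deterministic layout of one pot: per-plant and per-leaf geometry parameters
#' Lay out the seedlings of a pot
#'
#' Draws the per-plant and per-leaf geometry (grid positions with jitter,
#' stem lengths/radii/curvature directions, leaf attachment heights,
#' azimuths, arcs, widths) deterministically from the seed. The layout is
#' the ground-truth object: [analytic_traits()] evaluates it in closed form
#' and [generate_pot()] samples points from it.
#'
#' @param spec a [pot_spec()].
#' @param seed integer seed.
#' @return a `pot_layout` list of per-plant specifications.
#' @export
pot_layout <- function(spec, seed = 1L) {
  set.seed(seed)
  n <- spec$n_plants
  if (is.null(n)) n <- sample(15:25, 1L)
  grid <- expand.grid(x = seq_len(5L), y = seq_len(5L))
  cells <- grid[sample(nrow(grid), n), , drop = FALSE]
  pitch <- spec$tray[1L] / 5
  plants <- vector("list", n)
  for (i in seq_len(n)) {
    base <- c((cells$x[i] - 0.5) * pitch - spec$tray[1L] / 2,
              (cells$y[i] - 0.5) * pitch - spec$tray[2L] / 2) +
            stats::rnorm(2L, 0, spec$grid_jitter)
    L <- stats::runif(1L, spec$stem_length_range[1L], spec$stem_length_range[2L])
    nl_choices <- seq(spec$leaves_per_plant[1L], spec$leaves_per_plant[2L])
    nl <- nl_choices[sample.int(length(nl_choices), 1L)]
    az0 <- stats::runif(1L, 0, 2 * pi)
    leaves <- vector("list", nl)
    for (k in seq_len(nl)) {
      S <- stats::runif(1L, spec$leaf_arc_range[1L], spec$leaf_arc_range[2L])
      phi <- stats::runif(1L, spec$leaf_bend_angle_range[1L],
                          spec$leaf_bend_angle_range[2L])
      leaves[[k]] <- list(
        attach_frac = 0.45 + 0.25 * (k - 1L),
        azimuth = az0 + (k - 1L) * 2 * pi / nl +
                  stats::runif(1L, -0.2, 0.2),
        arc = S,
        width = stats::runif(1L, spec$leaf_width_range[1L],
                             spec$leaf_width_range[2L]),
        bend_radius = S / phi,
        theta0 = stats::runif(1L, 0.9, 1.2))   # initial elevation (rad)
    }
    plants[[i]] <- list(
      id = i, base = base,
      length = L,
      radius = stats::runif(1L, spec$stem_radius_range[1L],
                            spec$stem_radius_range[2L]),
      bend_azimuth = stats::runif(1L, 0, 2 * pi),
      bend = spec$stem_curvature * L,
      leaves = leaves)
  }
  structure(list(plants = plants, spec = spec, seed = seed),
            class = "pot_layout")
}

# stem centerline at parameter t in [0, 1]
.stem_center <- function(p, t) {
  cbind(p$base[1L] + p$bend * t^2 * cos(p$bend_azimuth),
        p$base[2L] + p$bend * t^2 * sin(p$bend_azimuth),
        p$length * t)
}

# leaf centerline at arc position s in [0, S]: circular arc of radius R in
# the vertical plane through the azimuth, starting at elevation theta0
.leaf_center <- function(attach, lf, s) {
  R <- lf$bend_radius
  th <- lf$theta0 - s / R
  er <- c(cos(lf$azimuth), sin(lf$azimuth), 0)
  radial <- R * (sin(lf$theta0) - sin(th))
  vert <- R * (cos(th) - cos(lf$theta0))
  cbind(attach[1L] + radial * er[1L],
        attach[2L] + radial * er[2L],
        attach[3L] + vert)
}

#' Closed-form traits of a pot layout
#'
#' Evaluates the ground-truth trait record without sampling any points:
#' per-plant stem length (axial extent of the centerline along its principal
#' direction) and diameter `2 r`; per-leaf chord length `2 R sin(S / 2R)`,
#' width `W` and surface area `S * W` (the ribbons are developable
#' cylinder sections); pot-level leaf count and `LAI = total area / 625 cm2`.
#'
#' @param layout a [pot_layout()].
#' @return a list shaped like a `trait_record`: data.frames `plants` and
#'   `leaves` plus the `pot` summary.
#' @export
analytic_traits <- function(layout) {
  plants <- do.call(rbind, lapply(layout$plants, function(p) {
    t <- seq(0, 1, length.out = 201L)
    cl <- .stem_center(p, t)
    ctr <- colMeans(cl)
    a <- svd(sweep(cl, 2L, ctr))$v[, 1L]
    proj <- sweep(cl, 2L, ctr) %*% a
    data.frame(plant = p$id,
               stem_length_cm = (max(proj) - min(proj)) * 100,
               stem_diameter_mm = 2 * p$radius * 1000,
               base_x = p$base[1L], base_y = p$base[2L])
  }))
  leaves <- do.call(rbind, lapply(layout$plants, function(p) {
    do.call(rbind, lapply(seq_along(p$leaves), function(k) {
      lf <- p$leaves[[k]]
      R <- lf$bend_radius
      data.frame(plant = p$id, leaf = k,
                 length_cm = 2 * R * sin(lf$arc / (2 * R)) * 100,
                 width_cm = lf$width * 100,
                 area_cm2 = lf$arc * lf$width * 1e4)
    }))
  }))
  rec <- list(plants = plants, leaves = leaves)
  rec$pot <- list(leaf_count = nrow(leaves),
                  lai = sum(leaves$area_cm2) / 625,
                  mean_stem_height_cm = mean(plants$stem_length_cm),
                  mean_stem_diameter_mm = mean(plants$stem_diameter_mm))
  rec
}

.jitter_colors <- function(base, n, sd = 18) {
  m <- matrix(rep(base, each = n), n, 3L) + matrix(stats::rnorm(3L * n, 0, sd), n, 3L)
  matrix(as.integer(pmin(pmax(round(m), 0), 255)), n, 3L)
}

#' Generate a labeled pot cloud
#'
#' Samples points from the layout's surfaces — stems on cylinder surfaces
#' (label 1), leaves on bent ribbons (label 0), the tray on a box shell
#' (label 2) — adds Gaussian surface noise, applies the height-dependent
#' density gradient and occlusion-sector thinning, and attaches plausible
#' per-class colors. Deterministic given the seed.
#'
#' @param spec a [pot_spec()].
#' @param seed integer seed.
#' @param layout optional precomputed [pot_layout()] (it is regenerated from
#'   the seed otherwise).
#' @param pot_id pot id stamped on the cloud, default `"pot<seed>"`.
#' @return a list with the labeled `cloud`, the ground-truth `traits`
#'   (from [analytic_traits()]), the `layout`, and per-point instance ids
#'   `point_plant` and `point_leaf` (0 = none).
#' @export
generate_pot <- function(spec = pot_spec(), seed = 1L, layout = NULL,
                         pot_id = NULL) {
  if (is.null(layout)) layout <- pot_layout(spec, seed)
  set.seed(seed + 1000003L)
  ds <- spec$density_scale
  pts <- list(); labs <- list(); plant_id <- list(); leaf_id <- list()
  for (p in layout$plants) {
    ns <- max(2L, as.integer(round(spec$points_per_stem * ds)))
    t <- stats::runif(ns)
    th <- stats::runif(ns, 0, 2 * pi)
    c0 <- .stem_center(p, t)
    stem <- c0 + cbind(p$radius * cos(th), p$radius * sin(th), 0)
    pts[[length(pts) + 1L]] <- stem
    labs[[length(labs) + 1L]] <- rep(1L, ns)
    plant_id[[length(plant_id) + 1L]] <- rep(p$id, ns)
    leaf_id[[length(leaf_id) + 1L]] <- rep(0L, ns)
    attach_top <- .stem_center(p, 1)[1L, ]
    for (k in seq_along(p$leaves)) {
      lf <- p$leaves[[k]]
      attach <- .stem_center(p, lf$attach_frac)[1L, ]
      # offset the ribbon start off the stem surface so sibling leaves stay
      # separable by the instancing radius
      attach <- attach + 0.008 * c(cos(lf$azimuth), sin(lf$azimuth), 0.4)
      nl <- max(4L, as.integer(round(spec$points_per_leaf * ds)))
      # edge-inclusive (s, w) grid: covers the full ribbon so surface area is
      # recovered without a sampling margin; the Delaunay estimator is
      # exercised on curvature, not on hull shrinkage
      ns_ <- max(2L, as.integer(round(sqrt(nl * lf$arc / lf$width))))
      nw_ <- max(2L, as.integer(ceiling(nl / ns_)))
      gsw <- expand.grid(s = seq(0, lf$arc, length.out = ns_),
                         w = seq(-lf$width / 2, lf$width / 2, length.out = nw_))
      s <- gsw$s; w <- gsw$w; nl <- length(s)
      cl <- .leaf_center(attach, lf, s)
      ew <- c(-sin(lf$azimuth), cos(lf$azimuth), 0)
      leaf <- cl + outer(w, ew)
      if (spec$wrinkle_amp > 0) {
        # normal of the ribbon at arc position s
        thv <- lf$theta0 - s / lf$bend_radius
        er <- c(cos(lf$azimuth), sin(lf$azimuth), 0)
        nrm <- cbind(-sin(thv) * er[1L], -sin(thv) * er[2L], cos(thv))
        leaf <- leaf + nrm * (spec$wrinkle_amp *
                                sin(2 * pi * 3 * s / lf$arc) *
                                sin(2 * pi * 2 * (w / lf$width + 0.5)))
      }
      pts[[length(pts) + 1L]] <- leaf
      labs[[length(labs) + 1L]] <- rep(0L, nl)
      plant_id[[length(plant_id) + 1L]] <- rep(p$id, nl)
      leaf_id[[length(leaf_id) + 1L]] <- rep(k, nl)
    }
  }
  # tray: bottom plus four shallow walls
  nt <- max(5L, as.integer(round(spec$tray_points * ds)))
  nb <- as.integer(round(nt * 0.7))
  tx <- spec$tray[1L] / 2; ty <- spec$tray[2L] / 2; tz <- spec$tray[3L]
  bottom <- cbind(stats::runif(nb, -tx, tx), stats::runif(nb, -ty, ty),
                  stats::rnorm(nb, -0.002, 2e-4))
  nw <- nt - nb
  side <- sample(4L, nw, replace = TRUE)
  u <- stats::runif(nw, -tx, tx); z <- stats::runif(nw, -tz, 0)
  wall <- cbind(ifelse(side == 1L, -tx, ifelse(side == 2L, tx, u)),
                ifelse(side <= 2L, u, ifelse(side == 3L, -ty, ty)), z)
  tray <- rbind(bottom, wall)
  pts[[length(pts) + 1L]] <- tray
  labs[[length(labs) + 1L]] <- rep(2L, nrow(tray))
  plant_id[[length(plant_id) + 1L]] <- rep(0L, nrow(tray))
  leaf_id[[length(leaf_id) + 1L]] <- rep(0L, nrow(tray))

  P <- do.call(rbind, pts)
  lab <- unlist(labs); pid <- unlist(plant_id); lid <- unlist(leaf_id)
  if (spec$noise_sigma > 0)
    P <- P + matrix(stats::rnorm(length(P), 0, spec$noise_sigma), ncol = 3L)

  # reconstruction artifacts: thin with height and inside occlusion sectors
  keep <- rep(TRUE, nrow(P))
  if (spec$density_gradient > 0) {
    zr <- range(P[, 3L])
    frac <- (P[, 3L] - zr[1L]) / max(zr[2L] - zr[1L], 1e-9)
    keep <- keep & (stats::runif(nrow(P)) > spec$density_gradient * frac)
  }
  if (spec$occlusion_sectors > 0L) {
    az <- atan2(P[, 2L], P[, 1L])
    for (sct in seq_len(spec$occlusion_sectors)) {
      a0 <- stats::runif(1L, -pi, pi)
      wdt <- stats::runif(1L, 0.3, 0.7)
      inside <- abs(((az - a0 + pi) %% (2 * pi)) - pi) < wdt / 2
      keep <- keep & !(inside & stats::runif(nrow(P)) < 0.7)
    }
  }
  P <- P[keep, , drop = FALSE]; lab <- lab[keep]; pid <- pid[keep]; lid <- lid[keep]

  cols <- matrix(0L, nrow(P), 3L)
  cols[lab == 0L, ] <- .jitter_colors(c(60, 160, 60), sum(lab == 0L))
  cols[lab == 1L, ] <- .jitter_colors(c(175, 190, 90), sum(lab == 1L))
  cols[lab == 2L, ] <- .jitter_colors(c(148, 148, 155), sum(lab == 2L))

  if (is.null(pot_id)) pot_id <- paste0("pot", seed)
  list(cloud = labeled_cloud(P, cols, lab, pot_id = pot_id),
       traits = analytic_traits(layout), layout = layout,
       point_plant = pid, point_leaf = lid)
}

#' Generate a benchmark dataset on disk
#'
#' Writes `n_pots` pot clouds as PLY files plus a ground-truth CSV (one row
#' per plant and leaf, analytic values) and a pot-level split manifest.
#'
#' @param n_pots number of pots (>= 3).
#' @param out_dir output directory (created if missing).
#' @param split_ratio train/val/test ratio, default `c(7, 2, 1)`.
#' @param seed integer seed; pot i uses seed `seed + i`.
#' @param spec a [pot_spec()].
#' @param fps_points FPS-downsample each written cloud to this many points
#'   (`NULL` keeps the dense cloud), default 4096.
#' @return invisibly, a list with the PLY `files`, the `split`, and the
#'   ground-truth data.frame.
#' @export
generate_benchmark <- function(n_pots, out_dir, split_ratio = c(7, 2, 1),
                               seed = 1L, spec = pot_spec(),
                               fps_points = 4096L) {
  if (n_pots < 3L) stop("need at least 3 pots")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n_pots)
  gt <- list()
  pot_ids <- sprintf("pot%03d", seq_len(n_pots))
  for (i in seq_len(n_pots)) {
    g <- generate_pot(spec, seed = seed + i, pot_id = pot_ids[i])
    cl <- g$cloud
    if (!is.null(fps_points)) cl <- fps_downsample(cl, fps_points, seed = seed + i)
    files[i] <- file.path(out_dir, paste0(pot_ids[i], ".ply"))
    write_ply(cl, files[i])
    pl <- g$traits$plants; pl$pot_id <- pot_ids[i]; pl$leaf <- NA_integer_
    lv <- g$traits$leaves; lv$pot_id <- pot_ids[i]
    gt[[length(gt) + 1L]] <- merge(pl, lv, all = TRUE, sort = FALSE)
  }
  split <- pot_level_split(pot_ids, split_ratio, seed)
  gt <- do.call(rbind, gt)
  utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(data.frame(pot_id = names(split$assignment),
                              subset = unname(split$assignment)),
                   file.path(out_dir, "split.csv"), row.names = FALSE)
  invisible(list(files = files, split = split, ground_truth = gt))
}
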