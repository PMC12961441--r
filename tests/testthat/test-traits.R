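test_that("rescale multiplies coordinates uniformly and validates", {
  cl <- random_cloud(5, seed = 1)
  expect_identical(rescale_cloud(cl, 1), cl)
  cl2 <- labeled_cloud(rbind(c(100, 0, 0)), labels = 1L)
  expect_equal(rescale_cloud(cl2, 0.01)$points, rbind(c(1, 0, 0)))
  expect_error(rescale_cloud(cl, 0), "positive")
})

test_that("split_by_label separates classes and excludes ignore points", {
  pts <- matrix(rnorm(60 * 3), 60, 3)
  labs <- rep(c(1L, 0L, 2L), times = c(10, 20, 30))
  cl <- labeled_cloud(pts, labels = labs)
  parts <- split_by_label(cl)
  expect_equal(nrow(parts$stem), 10L)
  expect_equal(nrow(parts$leaf), 20L)
  expect_equal(nrow(parts$pot), 30L)
  labs[1:5] <- -1L
  cl$labels <- labs
  parts2 <- split_by_label(cl)
  expect_equal(nrow(parts2$stem) + nrow(parts2$leaf) + nrow(parts2$pot), 55L)
  cl$labels <- rep(c(-1L, 0L, 2L), 20)
  expect_warning(split_by_label(cl), "no stem")
})

test_that("stem clustering follows DBSCAN semantics", {
  set.seed(51)
  b1 <- cbind(rnorm(100, 0, 0.004), rnorm(100, 0, 0.004), runif(100, 0, 0.04))
  b2 <- cbind(rnorm(100, 0.10, 0.004), rnorm(100, 0.10, 0.004), runif(100, 0, 0.04))
  plants <- cluster_stems(rbind(b1, b2), cluster_config(eps = 0.03, min_pts = 80))
  expect_length(plants, 2L)
  expect_equal(plants[[1]]$centroid, colMeans(b1[, 1:2]), tolerance = 1e-9)
  # 50 points with minPts = 80: everything is noise
  expect_length(cluster_stems(b1[1:50, ], cluster_config(0.03, 80)), 0L)
})

test_that("DBSCAN partition matches a from-scratch textbook implementation", {
  set.seed(52)
  for (r in 1:8) {
    n <- 120
    pts <- cbind(runif(n, 0, 0.2), runif(n, 0, 0.2))
    eps <- 0.02; mp <- 5L
    got <- ns$cpp_dbscan(pts, eps, mp)
    want <- oracle_dbscan(pts, eps, mp)
    expect_identical(got == -1L, want == -1L)       # same noise set
    # same partition up to cluster relabeling (core points determine it;
    # border points may legally attach to different adjacent clusters)
    D <- as.matrix(dist(pts))
    core <- rowSums(D <= eps) >= mp
    for (cl in unique(want[want > 0 & core])) {
      members <- which(want == cl & core)
      expect_length(unique(got[members]), 1L)
    }
    expect_equal(length(unique(got[got > 0])), length(unique(want[want > 0])))
  }
})

test_that("stem axis fitting recovers lines, rejects outliers, fixes the sign", {
  set.seed(53)
  # exact vertical line: axis recovered to numerical precision
  z <- seq(0, 0.04, length.out = 200)
  line <- cbind(0, 0, z)
  pl <- structure(list(id = 1L, points = line, centroid = c(0, 0)),
                  class = "plant_instance")
  fitl <- fit_stem_axis(pl, ransac_config(tau = 0.005, seed = 2))
  expect_lt(max(abs(fitl$axis - c(0, 0, 1))), 1e-6)
  # thin vertical cylinder surface
  vert <- cbind(0.001 * cos(seq_len(200)), 0.001 * sin(seq_len(200)), z)
  p <- structure(list(id = 1L, points = vert, centroid = c(0, 0)),
                 class = "plant_instance")
  fit <- fit_stem_axis(p, ransac_config(tau = 0.005, seed = 2))
  expect_lt(max(abs(fit$axis - c(0, 0, 1))), 1e-2)
  expect_gte(fit$axis[3], 0)
  # 10% far outliers are excluded from the consensus set
  out <- rbind(vert, matrix(runif(60, 0.05, 0.1), 20, 3))
  pf <- structure(list(id = 1L, points = out, centroid = c(0, 0)),
                  class = "plant_instance")
  fit2 <- fit_stem_axis(pf, ransac_config(tau = 0.005, seed = 3))
  expect_false(any(fit2$inliers[201:220]))
  ang <- acos(abs(sum(fit2$axis * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
  # downward-pointing stem comes back with a_z >= 0
  tilt <- cbind(z, 0, -z)
  pt <- structure(list(id = 1L, points = tilt, centroid = c(0, 0)),
                  class = "plant_instance")
  fit3 <- fit_stem_axis(pt, ransac_config(seed = 4))
  expect_gte(fit3$axis[3], 0)
  expect_error(fit_stem_axis(structure(list(points = vert[c(1, 1), ]),
                                       class = "plant_instance")),
               "coincident")
})

test_that("leaf assignment is nearest-centroid with lowest-id ties", {
  plants <- list(list(id = 1L, centroid = c(0, 0)),
                 list(id = 2L, centroid = c(0.05, 0)))
  lp <- rbind(c(0.01, 0, 0.02), c(0.045, 0, 0.02))
  expect_equal(assign_leaves(lp, plants), c(1L, 2L))
  # equidistant point goes to the lower plant id
  expect_equal(assign_leaves(rbind(c(0.025, 0, 0)), plants), 1L)
  # brute-force agreement on a random layout
  set.seed(54)
  plants10 <- lapply(1:10, function(i) list(id = i, centroid = runif(2, 0, 0.25)))
  lp <- cbind(runif(200, 0, 0.25), runif(200, 0, 0.25), runif(200, 0, 0.05))
  got <- assign_leaves(lp, plants10)
  cen <- do.call(rbind, lapply(plants10, `[[`, "centroid"))
  want <- apply(lp, 1, function(q)
    which.min((cen[, 1] - q[1])^2 + (cen[, 2] - q[2])^2))
  expect_equal(got, want)
  expect_warning(a <- assign_leaves(lp, list()), "no plants")
  expect_true(all(is.na(a)))
})

test_that("leaf instancing separates distant ribbons and merges touching ones", {
  set.seed(55)
  ribbon <- function(x0) cbind(runif(100, x0, x0 + 0.03),
                               runif(100, 0, 0.01), 0.02)
  two <- rbind(ribbon(0), ribbon(0.08))    # 5 cm gap
  expect_length(segment_leaves(two, eps = 0.01, min_pts = 20), 2L)
  expect_length(segment_leaves(ribbon(0), eps = 0.01, min_pts = 20), 1L)
  touching <- rbind(ribbon(0), ribbon(0.032))  # 2 mm gap < eps
  expect_length(segment_leaves(touching, eps = 0.01, min_pts = 20), 1L)
})

test_that("leaf dimensions give rectangle extents, invariant to 3-D rotation", {
  g <- as.matrix(expand.grid(x = seq(0, 0.04, length.out = 20),
                             y = seq(0, 0.01, length.out = 6)))
  leaf <- cbind(g, 0)
  d <- leaf_dimensions(leaf)
  expect_equal(d$length_cm, 4, tolerance = 1e-9)
  expect_equal(d$width_cm, 1, tolerance = 1e-9)
  expect_lt(abs(sum(d$u1 * d$u2)), 1e-9)       # orthogonal axes
  # arbitrary rotation
  th <- c(0.7, -1.1, 0.4)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  rot <- leaf %*% (Rx %*% Rz)
  dr <- leaf_dimensions(rot)
  expect_equal(dr$length_cm, 4, tolerance = 1e-6)
  expect_equal(dr$width_cm, 1, tolerance = 1e-6)
  expect_error(leaf_dimensions(leaf[1:2, ]), "at least 3")
})

test_that("Delaunay leaf area: single triangle, flat grid, curved ribbon", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  expect_equal(leaf_area(tri, to_cm2 = FALSE), 2.0, tolerance = 1e-12)
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = 11),
                             y = seq(0, 1, length.out = 11)))
  expect_equal(leaf_area(cbind(g, 0), to_cm2 = FALSE), 1.0, tolerance = 1e-9)
  # collinear points: zero area with a warning
  expect_warning(a0 <- leaf_area(cbind(1:5 / 100, 0, 0)), "collinear")
  expect_equal(a0, 0)
  # cylinder-section ribbon sampled by the generator at ~2000 points
  sp <- pot_spec(n_plants = 1, noise_sigma = 0, stem_curvature = 0,
                 density_gradient = 0, occlusion_sectors = 0, grid_jitter = 0,
                 leaves_per_plant = c(1L, 1L), points_per_leaf = 2000L)
  gpot <- generate_pot(sp, seed = 5)
  lf <- gpot$cloud$points[gpot$cloud$labels == 0L, ]
  truth <- gpot$traits$leaves
  expect_lt(abs(leaf_area(lf) / truth$area_cm2 - 1), 0.02)
  dd <- leaf_dimensions(lf)
  expect_lt(abs(dd$length_cm / truth$length_cm - 1), 0.05)
})

test_that("stem traits recover the analytic cylinder", {
  set.seed(56)
  n <- 400
  th <- runif(n, 0, 2 * pi)
  cyl <- cbind(0.001 * cos(th), 0.001 * sin(th), runif(n, 0, 0.04))
  p <- structure(list(id = 1L, points = cyl, centroid = c(0, 0)),
                 class = "plant_instance")
  p <- fit_stem_axis(p, ransac_config(seed = 1))
  st <- stem_traits(p)
  expect_lt(abs(st$stem_length_cm - 4), 0.1)
  expect_lt(abs(st$stem_diameter_mm - 2), 0.1)
  # noisy surface: diameter within 10%
  cyl_n <- cyl + matrix(rnorm(3 * n, 0, 1e-4), n, 3)
  pn <- structure(list(id = 1L, points = cyl_n, centroid = c(0, 0)),
                  class = "plant_instance")
  pn <- fit_stem_axis(pn, ransac_config(seed = 1))
  expect_lt(abs(stem_traits(pn)$stem_diameter_mm / 2 - 1), 0.1)
  # degenerate two-point stem
  p2 <- structure(list(id = 1L, points = rbind(c(0, 0, 0), c(0, 0, 0.03)),
                       centroid = c(0, 0)),
                  class = "plant_instance")
  p2 <- fit_stem_axis(p2, ransac_config(seed = 1))
  st2 <- stem_traits(p2)
  expect_equal(st2$stem_length_cm, 3, tolerance = 1e-9)
  expect_equal(st2$stem_diameter_mm, 0, tolerance = 1e-9)
})

test_that("pot summary implements the LAI definition", {
  rec <- list(leaves = data.frame(area_cm2 = c(300, 325)),
              plants = data.frame(stem_length_cm = c(4, 5),
                                  stem_diameter_mm = c(2, 3)))
  s <- pot_summary(rec)
  expect_equal(s$lai, 1.0)
  expect_equal(s$leaf_count, 2L)
  expect_equal(s$mean_stem_height_cm, 4.5)
  expect_equal(pot_summary(list(leaves = data.frame(area_cm2 = 1831.25)))$lai,
               2.93)
  z <- pot_summary(list(leaves = NULL, plants = NULL))
  expect_equal(z$lai, 0); expect_equal(z$leaf_count, 0L)
})

test_that("traits are invariant to rigid motion about z and commute with rescale", {
  sp <- pot_spec(n_plants = 6, noise_sigma = 0, stem_curvature = 0,
                 density_scale = 2, density_gradient = 0, occlusion_sectors = 0,
                 grid_jitter = 5e-4, leaf_arc_range = c(0.02, 0.03),
                 leaf_bend_angle_range = c(0.3, 0.6))
  g <- generate_pot(sp, seed = 77)
  rec <- extract_traits(g$cloud)
  th <- 0.6
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cl2 <- g$cloud
  cl2$points <- sweep(cl2$points %*% t(Rz), 2, c(0.3, -0.2, 0.1), `+`)
  rec2 <- extract_traits(cl2)
  expect_equal(nrow(rec2$plants), nrow(rec$plants))
  expect_equal(sort(rec2$plants$stem_length_cm), sort(rec$plants$stem_length_cm),
               tolerance = 1e-6)
  expect_equal(rec2$pot$lai, rec$pot$lai, tolerance = 1e-5)
  # pipeline on a pre-scaled cloud with scale 1 equals raw cloud with the factor
  half <- g$cloud; half$points <- half$points / 2
  rec3 <- extract_traits(half, scale = 2)
  expect_equal(rec3$pot$lai, rec$pot$lai, tolerance = 1e-9)
})

test_that("leaf count is exact on a well-separated pot", {
  sp <- pot_spec(n_plants = 4, noise_sigma = 0, stem_curvature = 0,
                 density_scale = 2, density_gradient = 0, occlusion_sectors = 0,
                 grid_jitter = 0, leaf_arc_range = c(0.018, 0.024),
                 leaf_bend_angle_range = c(0.3, 0.5))
  ok <- 0L
  for (s in 1:5) {
    g <- generate_pot(sp, seed = 300 + s)
    rec <- extract_traits(g$cloud)
    if (!is.null(rec$leaves) && nrow(rec$leaves) == nrow(g$traits$leaves))
      ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})
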