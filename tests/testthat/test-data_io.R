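test_that("labeled_cloud enforces its invariants", {
  expect_error(labeled_cloud(matrix(c(1, 2), 1, 2)), "three columns")
  expect_error(labeled_cloud(matrix(NA_real_, 1, 3)), "finite")
  expect_error(labeled_cloud(matrix(0, 1, 3), matrix(300L, 1, 3)), "255")
  expect_error(labeled_cloud(matrix(0, 1, 3), labels = 5L), "-1, 0, 1, 2")
  cl <- labeled_cloud(matrix(0, 2, 3))
  expect_identical(cl$labels, c(-1L, -1L))
  expect_true(all(cl$colors == 0L))
})

test_that("PLY write/read round-trips both dialects exactly", {
  cl <- random_cloud(10, seed = 3)
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_ply(cl, path, binary = binary)
    back <- read_ply(path)
    expect_lt(max(abs(back$points - cl$points)), 1e-6)
    expect_identical(back$colors, cl$colors)
    expect_identical(back$labels, cl$labels)
  }
})

test_that("PLY without color/label yields declared defaults", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "1 2 3"), path)
  cl <- read_ply(path)
  expect_true(all(cl$colors == 0L))
  expect_true(all(cl$labels == -1L))
  expect_equal(cl$points[2, ], c(1, 2, 3))
})

test_that("independently written ASCII and binary PLY parse identically", {
  cl <- random_cloud(25, seed = 9)
  cl$points <- round(cl$points, 3)  # exactly representable in float32 text
  pa <- withr::local_tempfile(fileext = ".ply")
  pb <- withr::local_tempfile(fileext = ".ply")
  oracle_write_ply_ascii(cl, pa)
  oracle_write_ply_binary(cl, pb)
  a <- read_ply(pa); b <- read_ply(pb)
  expect_lt(max(abs(a$points - b$points)), 1e-6)
  expect_identical(a$colors, b$colors)
  expect_identical(a$labels, b$labels)
  expect_identical(a$labels, cl$labels)
})

test_that("read_ply rejects files without coordinates", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "end_header", "0 0"),
             path)
  expect_error(read_ply(path), "x/y/z")
  expect_error(read_ply(file.path(tempdir(), "absent.ply")), "cannot read")
})

test_that("palette decoding maps exact colors, ignores the rest, round-trips", {
  cl <- labeled_cloud(matrix(0, 3, 3),
                      rbind(c(0L, 255L, 0L), c(10L, 10L, 10L), c(255L, 0L, 0L)))
  dec <- colors_to_labels(cl)
  expect_identical(dec$labels, c(1L, -1L, 0L))
  set.seed(1)
  cl2 <- labeled_cloud(matrix(rnorm(60), 20, 3),
                       labels = sample(c(-1L, 0:2), 20, replace = TRUE))
  rt <- colors_to_labels(labels_to_colors(cl2))
  expect_identical(rt$labels, cl2$labels)
})

test_that("FPS honors identity, the square example, and the size contract", {
  cl <- random_cloud(100, seed = 1)
  expect_identical(fps_downsample(cl, 100), cl)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_identical(fps_indices(sq, 3, start = 1L), c(1L, 4L, 2L))
  big <- random_cloud(10000, seed = 2)
  sub <- fps_downsample(big, 4096, seed = 7)
  expect_equal(n_points(sub), 4096L)
  key <- function(p) paste(p[, 1], p[, 2], p[, 3])
  expect_true(all(key(sub$points) %in% key(big$points)))
  expect_error(fps_downsample(cl, 0), "positive")
})

test_that("FPS matches the exhaustive greedy max-min oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    pts <- matrix(rnorm(8 * 3), 8, 3)
    expect_identical(fps_indices(pts, 5, start = 2L),
                     as.integer(oracle_fps(pts, 5, 2L)))
  }
})

test_that("FPS selections dominate random subsets in min pairwise distance", {
  set.seed(42)
  wins <- 0L
  for (r in 1:50) {
    pts <- matrix(runif(60 * 3), 60, 3)
    sel <- fps_indices(pts, 8, start = 1L)
    dmin <- min(dist(pts[sel, ]))
    rnd <- replicate(100, min(dist(pts[sample(60, 8), ])))
    if (dmin >= max(rnd)) wins <- wins + 1L
  }
  expect_gte(wins, 48L)   # greedy max-min coverage beats random essentially always
})

test_that("pot-level split gives 35/10/5 for 50 pots and never splits a pot", {
  sp <- pot_level_split(sprintf("pot%02d", 1:50), seed = 4)
  expect_equal(as.vector(table(sp$assignment)[c("train", "val", "test")]),
               c(35L, 10L, 5L))
  sp2 <- pot_level_split(sprintf("pot%02d", 1:50), seed = 4)
  expect_identical(sp$assignment, sp2$assignment)
  # 10 pots -> 7/2/1 by the floor-val/test rule
  sp10 <- pot_level_split(paste0("p", 1:10), seed = 1)
  expect_equal(as.vector(table(sp10$assignment)[c("train", "val", "test")]),
               c(7L, 2L, 1L))
  # timepoints of one pot always share the subset
  pots <- rep(paste0("p", 1:10), each = 7)   # 7 timepoints each
  spt <- pot_level_split(pots, seed = 2)
  per_pot <- tapply(spt$assignment[pots], pots, function(x) length(unique(x)))
  expect_true(all(per_pot == 1L))
  expect_error(pot_level_split(c("a", "b")), "at least 3")
})

test_that("augmentations respect their bounds and preserve labels", {
  cl <- random_cloud(1e5, seed = 5)
  cfg <- augment_config(scale_range = c(1, 1), flip_prob = 0,
                        elastic_params = list(), sphere_crop_max = 2e5)
  set.seed(1)
  out <- augment(cl, cfg)
  expect_identical(out$labels, cl$labels)
  expect_lte(max(abs(out$points - cl$points)), 0.02 + 1e-12)  # jitter clip
  # flip_prob = 0 and no jitter: coordinates unchanged
  cfg0 <- augment_config(scale_range = c(1, 1), flip_prob = 0,
                         jitter_sigma = 0, elastic_params = list(),
                         sphere_crop_max = 2e5)
  expect_equal(augment(cl, cfg0)$points, cl$points)
  # scale is one factor per cloud
  cfgs <- augment_config(flip_prob = 0, jitter_sigma = 0, elastic_params = list(),
                         sphere_crop_max = 2e5)
  set.seed(2)
  sc <- augment(cl, cfgs)
  ratio <- sc$points / cl$points
  ratio <- ratio[is.finite(ratio)]
  expect_lt(diff(range(ratio)), 1e-12)
  expect_gte(min(ratio), 0.9); expect_lte(max(ratio), 1.1)
})

test_that("sphere crop returns the cap count of nearest points and keeps label multiset", {
  cl <- random_cloud(1000, seed = 6)
  cfg <- augment_config(scale_range = c(1, 1), flip_prob = 0, jitter_sigma = 0,
                        elastic_params = list(), sphere_crop_max = 800L)
  set.seed(3)
  out <- augment(cl, cfg)
  expect_equal(n_points(out), 800L)
  key <- function(p) paste(round(p[, 1], 10), round(p[, 2], 10))
  m <- match(key(out$points), key(cl$points))
  expect_false(anyNA(m))
  expect_identical(out$labels, cl$labels[m])   # labels follow surviving points
  # the kept set is a metric ball: some kept point works as a center whose
  # 800 nearest input points are exactly the kept points
  kept <- sort(m)
  centers_ok <- any(vapply(kept, function(ctr) {
    d2 <- rowSums(sweep(cl$points, 2, cl$points[ctr, ])^2)
    setequal(order(d2)[1:800], kept)
  }, logical(1)))
  expect_true(centers_ok)
})

test_that("elastic distortion displaces smoothly without changing counts", {
  cl <- random_cloud(500, seed = 8)
  cfg <- augment_config(scale_range = c(1, 1), flip_prob = 0, jitter_sigma = 0)
  set.seed(4)
  out <- augment(cl, cfg)
  expect_equal(n_points(out), 500L)
  expect_identical(out$labels, cl$labels)
  expect_false(isTRUE(all.equal(out$points, cl$points)))
})
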