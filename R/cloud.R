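#' Labeled point cloud
#'
#' The universal exchange object of the package: an N x 3 coordinate matrix in
#' meters, per-point RGB colors in \[0, 255\], and per-point integer class
#' labels. The label vocabulary is \code{0 = leaf}, \code{1 = stem},
#' \code{2 = pot}, with \code{-1} marking points ignored by training and
#' evaluation.
#'
#' @param points numeric N x 3 matrix of xyz coordinates (meters); all finite.
#' @param colors integer N x 3 matrix of RGB values in \[0, 255\]; defaults to
#'   all zeros when absent.
#' @param labels integer vector of length N with values in \{-1, 0, 1, 2\};
#'   defaults to all \code{-1} (ignore) when absent.
#' @param pot_id character scalar naming the physical pot the cloud came from.
#' @param timepoint optional character scalar (acquisition time tag).
#' @return An object of class \code{labeled_cloud}.
#' @export
labeled_cloud <- function(points, colors = NULL, labels = NULL,
                          pot_id = "pot", timepoint = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3L) stop("`points` must have three columns (x, y, z)")
  n <- nrow(points)
  if (n < 1L) stop("a labeled_cloud needs at least one point")
  if (!all(is.finite(points))) stop("`points` must be finite")
  if (is.null(colors)) colors <- matrix(0L, n, 3L)
  colors <- as.matrix(colors)
  storage.mode(colors) <- "integer"
  dimnames(colors) <- NULL
  if (!all(dim(colors) == c(n, 3L))) stop("`colors` must be N x 3")
  if (any(colors < 0L | colors > 255L)) stop("`colors` must lie in [0, 255]")
  if (is.null(labels)) labels <- rep(-1L, n)
  labels <- as.integer(labels)
  names(labels) <- NULL
  if (length(labels) != n) stop("`labels` must have one entry per point")
  if (!all(labels %in% c(-1L, 0L, 1L, 2L)))
    stop("`labels` must be in {-1, 0, 1, 2}")
  structure(list(points = points, colors = colors, labels = labels,
                 pot_id = as.character(pot_id)[1L],
                 timepoint = if (is.null(timepoint)) NULL else as.character(timepoint)[1L]),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(-1L, 0L, 1L, 2L)))
  cat(sprintf("<labeled_cloud> %d points, pot '%s'%s\n", nrow(x$points), x$pot_id,
              if (is.null(x$timepoint)) "" else paste0(" @ ", x$timepoint)))
  cat(sprintf("  labels: ignore=%d leaf=%d stem=%d pot=%d\n",
              tab[["-1"]], tab[["0"]], tab[["1"]], tab[["2"]]))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a \code{labeled_cloud}.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Class palette
#'
#' Bijective mapping between the three semantic classes and display colors:
#' leaf = red (255,0,0), stem = green (0,255,0), pot = yellow (255,255,0).
#' Used for exact ("bitwise") color/label matching when clouds are exchanged
#' as colored PLY files.
#'
#' @return a named list with a 3 x 3 integer \code{rgb} matrix (rows in class
#'   order leaf, stem, pot) and the integer \code{classes} 0:2.
#' @export
class_palette <- function() {
  rgb <- rbind(leaf = c(255L, 0L, 0L),
               stem = c(0L, 255L, 0L),
               pot  = c(255L, 255L, 0L))
  list(rgb = rgb, classes = 0:2)
}

#' Map palette colors to class labels
#'
#' Exact RGB matches against the palette become the corresponding class label;
#' any other color becomes the ignore label \code{-1}.
#'
#' @param cloud a \code{labeled_cloud}.
#' @param palette a palette from [class_palette()].
#' @return the cloud with \code{labels} replaced by the decoded labels.
#' @export
colors_to_labels <- function(cloud, palette = class_palette()) {
  key <- cloud$colors[, 1L] * 65536L + cloud$colors[, 2L] * 256L + cloud$colors[, 3L]
  pkey <- palette$rgb[, 1L] * 65536L + palette$rgb[, 2L] * 256L + palette$rgb[, 3L]
  idx <- match(key, pkey)
  cloud$labels <- ifelse(is.na(idx), -1L, palette$classes[idx])
  cloud
}

#' Paint class labels as palette colors
#'
#' Inverse of [colors_to_labels()]: labeled points receive exactly the palette
#' color of their class; ignore-labeled points are painted black (0,0,0),
#' which is not a palette color and therefore decodes back to \code{-1}.
#'
#' @inheritParams colors_to_labels
#' @return the cloud with \code{colors} replaced.
#' @export
labels_to_colors <- function(cloud, palette = class_palette()) {
  cols <- matrix(0L, n_points(cloud), 3L)
  keep <- cloud$labels >= 0L
  if (any(keep))
    cols[keep, ] <- palette$rgb[match(cloud$labels[keep], palette$classes), , drop = FALSE]
  cloud$colors <- cols
  cloud
}

#' Subset a cloud by point index
#' @param cloud a \code{labeled_cloud}.
#' @param idx integer indices of points to keep.
#' @return the subset cloud (same pot/timepoint metadata).
#' @export
cloud_subset <- function(cloud, idx) {
  labeled_cloud(cloud$points[idx, , drop = FALSE],
                cloud$colors[idx, , drop = FALSE],
                cloud$labels[idx],
                pot_id = cloud$pot_id, timepoint = cloud$timepoint)
}

#' Uniformly rescale cloud coordinates
#'
#' Multi-view reconstruction yields coordinates up to a uniform scale; trait
#' extraction assumes meters, so clouds are rescaled by a constant factor
#' first. Colors and labels are untouched.
#'
#' @param cloud a \code{labeled_cloud}.
#' @param scale positive scalar factor applied to all coordinates.
#' @return the rescaled cloud.
#' @export
rescale_cloud <- function(cloud, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a positive finite scalar")
  cloud$points <- cloud$points * scale
  cloud
}
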