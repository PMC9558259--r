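#' Axis-aligned region-of-interest box
#'
#' With a fixed camera-to-scene geometry the region of interest is a fixed
#' axis-aligned box; a pass-through filter against it separates the potted
#' plant and its soil from the rest of the scene.
#'
#' @param xlim,ylim,zlim numeric length-2 vectors, `min <= max`, in meters.
#' @return an object of class `roi_box`.
#' @export
roi_box <- function(xlim, ylim, zlim) {
  lim <- list(xlim = xlim, ylim = ylim, zlim = zlim)
  for (nm in names(lim)) {
    v <- lim[[nm]]
    if (length(v) != 2L || anyNA(v) || v[1] > v[2])
      stop(nm, " must be a length-2 vector with min <= max")
  }
  structure(lim, class = "roi_box")
}

#' Pass-through (crop) filter
#'
#' Keeps exactly the points whose three coordinates lie inside the closed
#' box, preserving input order. Points exactly on a box face are kept.
#'
#' @param cloud a [point_cloud].
#' @param box an [roi_box].
#' @return the cropped [point_cloud] (possibly empty).
#' @export
passthrough_filter <- function(cloud, box) {
  if (!inherits(box, "roi_box")) stop("box must be an roi_box")
  p <- cloud$positions
  keep <- p[, 1] >= box$xlim[1] & p[, 1] <= box$xlim[2] &
    p[, 2] >= box$ylim[1] & p[, 2] <= box$ylim[2] &
    p[, 3] >= box$zlim[1] & p[, 3] <= box$zlim[2]
  subset_cloud(cloud, which(keep))
}

#' Color-based region growing segmentation
#'
#' Clusters are the connected components of the graph joining points that
#' are within `spatial_radius` of each other and whose RGB colors differ by
#' at most `color_threshold` (Euclidean distance in raw RGB). Because
#' clusters are maximal connected components, the result does not depend on
#' any seed order. Components smaller than `min_cluster_size` are dropped.
#'
#' @param cloud a [point_cloud] with colors.
#' @param spatial_radius neighbor hop radius (m).
#' @param color_threshold maximum endpoint color distance per hop (RGB units).
#' @param min_cluster_size smallest cluster retained (points).
#' @return list of integer index vectors (ascending), one per cluster,
#'   ordered by their smallest member index.
#' @export
region_grow_color <- function(cloud, spatial_radius = 0.005,
                              color_threshold = 40, min_cluster_size = 50) {
  if (!has_colors(cloud)) stop("region growing requires a colored cloud")
  if (spatial_radius <= 0) stop("spatial_radius must be > 0")
  if (color_threshold < 0) stop("color_threshold must be >= 0")
  if (n_points(cloud) == 0L) return(list())
  lab <- cpp_region_grow(cloud$positions, cloud$colors + 0.0,
                         spatial_radius, color_threshold)
  groups <- split(seq_along(lab), lab)
  groups <- groups[lengths(groups) >= min_cluster_size]
  groups <- groups[order(vapply(groups, min, integer(1)))]
  unname(lapply(groups, as.integer))
}

# ExG (excess green, 2G - R - B) of an n x 3 RGB matrix
rgb_exg <- function(colors) 2 * as.numeric(colors[, 2]) -
  as.numeric(colors[, 1]) - as.numeric(colors[, 3])

#' Split clusters into plant and soil by mean excess green
#'
#' A cluster whose mean per-point ExG (2G - R - B) is positive is
#' vegetation; otherwise it is soil. Reusing the ExG index here avoids a
#' second free color parameter.
#'
#' @param clusters list of index vectors as returned by
#'   [region_grow_color()].
#' @param cloud the colored [point_cloud] the indices refer to.
#' @return a list with elements `plant` and `soil` ([point_cloud]s, in the
#'   order the points appear in `cloud`) and `cluster_labels`, an integer
#'   vector over all input points (cluster number, or -1 if unassigned).
#' @export
classify_plant_soil <- function(clusters, cloud) {
  if (length(clusters) == 0L) stop("no clusters to classify")
  if (!has_colors(cloud)) stop("cloud must have colors")
  labels <- rep(-1L, n_points(cloud))
  is_plant <- logical(length(clusters))
  for (k in seq_along(clusters)) {
    idx <- clusters[[k]]
    labels[idx] <- k
    is_plant[k] <- mean(rgb_exg(cloud$colors[idx, , drop = FALSE])) > 0
  }
  plant_idx <- sort(unlist(clusters[is_plant], use.names = FALSE))
  soil_idx <- sort(unlist(clusters[!is_plant], use.names = FALSE))
  list(plant = subset_cloud(cloud, plant_idx),
       soil = subset_cloud(cloud, soil_idx),
       cluster_labels = labels)
}

#' Statistical outlier removal
#'
#' For every point the mean distance to its `k_neighbors` nearest neighbors
#' is computed; points whose mean exceeds the global mean of those means
#' plus `std_multiplier` standard deviations (strictly) are removed. With a
#' perfectly uniform cloud the standard deviation is zero and nothing is
#' removed.
#'
#' @param cloud a [point_cloud] with more than `k_neighbors` points.
#' @param k_neighbors neighborhood size (default 20).
#' @param std_multiplier threshold multiplier (default 1), > 0.
#' @return the filtered [point_cloud], a subset in original order.
#' @export
statistical_outlier_removal <- function(cloud, k_neighbors = 20,
                                        std_multiplier = 1.0) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (std_multiplier <= 0) stop("std_multiplier must be > 0")
  if (n_points(cloud) <= k_neighbors)
    stop("cloud must have more than k_neighbors points")
  md <- cpp_knn_mean_dist(cloud$positions, as.integer(k_neighbors))
  thr <- mean(md) + std_multiplier * stats::sd(md)
  subset_cloud(cloud, which(md <= thr))
}
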