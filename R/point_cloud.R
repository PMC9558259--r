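#' Colored 3D point cloud
#'
#' The universal currency of the pipeline: an n x 3 matrix of positions in
#' meters, optional per-point RGB colors (integers 0-255), and a coordinate
#' frame tag. In the `world` frame Z increases upward (height); sensor
#' clouds typically arrive in the `camera` frame where Z is distance from a
#' downward-looking camera.
#'
#' @param positions numeric matrix (or coercible) with 3 columns, in meters.
#' @param colors optional integer matrix with 3 columns (R, G, B in 0-255),
#'   one row per point.
#' @param frame `"camera"` or `"world"`.
#' @return An object of class `point_cloud`: a list with elements
#'   `positions`, `colors` (possibly `NULL`) and `frame`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(0.1, 0, 0.02)),
#'                   colors = rbind(c(60, 160, 70), c(120, 90, 60)),
#'                   frame = "world")
#' n_points(pc)
#' @export
point_cloud <- function(positions, colors = NULL, frame = c("camera", "world")) {
  frame <- match.arg(frame)
  positions <- as.matrix(positions)
  if (length(positions) == 0L) positions <- matrix(numeric(0), 0L, 3L)
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  dimnames(positions) <- NULL
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (ncol(colors) != 3L) stop("colors must have 3 columns")
    if (nrow(colors) != nrow(positions))
      stop("colors must have exactly one RGB triple per position")
    if (anyNA(colors) || any(colors < 0) || any(colors > 255))
      stop("color channels must lie in [0, 255]")
    storage.mode(colors) <- "integer"
    dimnames(colors) <- NULL
  }
  structure(list(positions = positions, colors = colors, frame = frame),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud].
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$positions)

#' Does a cloud carry per-point colors?
#' @param cloud a [point_cloud].
#' @return logical.
#' @export
has_colors <- function(cloud) !is.null(cloud$colors)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, %s colors, frame = %s\n",
              n_points(x), if (has_colors(x)) "with" else "no", x$frame))
  invisible(x)
}

# subset a cloud by index vector, preserving order and colors
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$positions[idx, , drop = FALSE],
              colors = if (has_colors(cloud)) cloud$colors[idx, , drop = FALSE],
              frame = cloud$frame)
}

# row-bind clouds; colors kept only if all parts have them
bind_clouds <- function(...) {
  parts <- Filter(function(p) !is.null(p) && n_points(p) > 0, list(...))
  if (length(parts) == 0L) stop("no points to bind")
  pos <- do.call(rbind, lapply(parts, function(p) p$positions))
  cols <- NULL
  if (all(vapply(parts, has_colors, logical(1))))
    cols <- do.call(rbind, lapply(parts, function(p) p$colors))
  point_cloud(pos, colors = cols, frame = parts[[1]]$frame)
}

#' Convert a camera-frame cloud to the Z-up world frame
#'
#' Top-view sensors report Z as distance from the camera, increasing
#' downward toward the soil; all height arithmetic in this package assumes
#' Z increasing upward. The conversion is `z_world = z_offset - z_camera`,
#' applied once at ingest.
#'
#' @param cloud a [point_cloud] in the camera frame.
#' @param z_offset height of the camera origin above the world origin (m).
#' @return the cloud in the world frame.
#' @export
to_world_frame <- function(cloud, z_offset = 0) {
  if (cloud$frame == "world") return(cloud)
  pos <- cloud$positions
  pos[, 3] <- z_offset - pos[, 3]
  point_cloud(pos, colors = cloud$colors, frame = "world")
}

#' Greedy radius downsampling
#'
#' Scans points in input order and keeps a point only when all previously
#' kept points lie at least `radius` away. Kept points are therefore a
#' subset of the input (provenance of original versus completed points is
#' preserved), pairwise separated by at least `radius`, and every discarded
#' point lies within `radius` of some kept point.
#'
#' @param cloud a [point_cloud].
#' @param radius minimum pairwise separation to enforce (m), > 0.
#' @return the downsampled [point_cloud].
#' @export
radius_downsample <- function(cloud, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a single value > 0")
  if (n_points(cloud) == 0L) return(cloud)
  keep <- cpp_radius_downsample(cloud$positions, radius)
  subset_cloud(cloud, keep)
}

#' Median nearest-neighbor spacing of a cloud
#'
#' Used as the density-matched default for completion fill spacing and the
#' final downsampling radius.
#'
#' @param cloud a [point_cloud] with at least 2 points.
#' @return median distance to the nearest neighbor (m).
#' @export
median_point_spacing <- function(cloud) {
  if (n_points(cloud) < 2L) stop("need at least 2 points")
  stats::median(cpp_knn_mean_dist(cloud$positions, 1L))
}

#' Sampling pitch of a cloud
#'
#' A robust upper envelope of the nearest-neighbor distances (90th
#' percentile by default). Unlike the median, it is not dragged down by
#' locally densified spots (boundary samples, completion fill points), so
#' it reflects the pitch a surface triangulation must bridge.
#'
#' @param cloud a [point_cloud] with at least 2 points.
#' @param probs quantile of the nearest-neighbor distances.
#' @return pitch in meters.
#' @export
point_pitch <- function(cloud, probs = 0.9) {
  if (n_points(cloud) < 2L) stop("need at least 2 points")
  unname(stats::quantile(cpp_knn_mean_dist(cloud$positions, 1L), probs))
}
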