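#' Completion configuration
#'
#' Parameters steering root-anchored leaf completion. Lengths are meters.
#'
#' @param var_mul edge-threshold multiplier in `d_TH = d_min + var_mul *
#'   sigma`; larger values admit more points into the closest edge. >= 0.
#' @param mu symmetry threshold on the imbalance ratio delta; a leaf with
#'   delta above `mu` is treated as asymmetric and mirrored (default 0.23).
#' @param n_s number of root-nearest points searched for the hole-boundary
#'   start point (default 20).
#' @param search_radius neighbor radius of the hole-boundary march; `NA`
#'   (default) resolves to 3 x `fill_spacing`.
#' @param fill_spacing spacing of uniformly sampled fill points; `NA`
#'   (default) resolves to the median nearest-neighbor spacing of the input
#'   plant cloud, so synthetic density matches sensor density.
#' @param completion_distance_fraction leaves whose centroid-to-root
#'   horizontal distance is at least this fraction of the maximum such
#'   distance are completed (outer leaves only); in (0, 1].
#' @param final_downsample_radius radius of the per-plant downsampling after
#'   completion; `NA` resolves to 0.5 x `fill_spacing`. Kept below the
#'   sensor spacing so only completion's repeated sampling is culled, never
#'   original surface detail.
#' @param angular_bins azimuthal bins used to screen edge points so no two
#'   survivors share a fill ray (default 144, i.e. 2.5 degrees: adjacent
#'   fill rays must stay closer than the meshing edge threshold at the
#'   edge radius, or the filled surface cannot be triangulated).
#' @param sigma_mode `"std"` (default): sigma in the edge threshold is the
#'   sample standard deviation of the point-to-root distances; `"printed"`:
#'   the scaled distance sum `sum(d)/(n - 1)`.
#' @param leaf_spatial_radius,leaf_color_threshold,leaf_min_cluster_size
#'   tightened region-growing settings for single-leaf segmentation.
#' @return an object of class `completion_config`.
#' @export
completion_config <- function(var_mul = 1.0, mu = 0.23, n_s = 20,
                              search_radius = NA_real_,
                              fill_spacing = NA_real_,
                              completion_distance_fraction = 0.5,
                              final_downsample_radius = NA_real_,
                              angular_bins = 144,
                              sigma_mode = c("std", "printed"),
                              leaf_spatial_radius = 0.0035,
                              leaf_color_threshold = 12,
                              leaf_min_cluster_size = 30) {
  sigma_mode <- match.arg(sigma_mode)
  if (var_mul < 0) stop("var_mul must be >= 0")
  if (mu <= 0 || mu >= 2) stop("mu must lie in (0, 2)")
  if (n_s < 1) stop("n_s must be >= 1")
  if (completion_distance_fraction <= 0 || completion_distance_fraction > 1)
    stop("completion_distance_fraction must lie in (0, 1]")
  if (angular_bins < 1) stop("angular_bins must be >= 1")
  for (v in c(search_radius, fill_spacing, final_downsample_radius))
    if (!is.na(v) && v <= 0) stop("lengths must be strictly positive")
  structure(list(var_mul = var_mul, mu = mu, n_s = as.integer(n_s),
                 search_radius = search_radius, fill_spacing = fill_spacing,
                 completion_distance_fraction = completion_distance_fraction,
                 final_downsample_radius = final_downsample_radius,
                 angular_bins = as.integer(angular_bins),
                 sigma_mode = sigma_mode,
                 leaf_spatial_radius = leaf_spatial_radius,
                 leaf_color_threshold = leaf_color_threshold,
                 leaf_min_cluster_size = leaf_min_cluster_size),
            class = "completion_config")
}

# fill runtime defaults that depend on the scene's point density
resolve_completion_config <- function(config, plant) {
  if (is.na(config$fill_spacing))
    config$fill_spacing <- median_point_spacing(plant)
  if (is.na(config$search_radius))
    config$search_radius <- 3 * config$fill_spacing
  if (is.na(config$final_downsample_radius))
    config$final_downsample_radius <- 0.5 * config$fill_spacing
  config
}

#' Estimate the root point of a rosette plant
#'
#' Rosette leaves grow evenly outward from the root crown, so the root's
#' horizontal position is the centroid of the plant cloud seen from above;
#' its height is the mean soil height (the soil surface is flat).
#'
#' @param plant,soil non-empty [point_cloud]s in the world frame.
#' @return numeric `c(x, y, z)` of class `root_point`.
#' @export
estimate_root <- function(plant, soil) {
  if (n_points(plant) == 0L) stop("plant cloud is empty")
  if (n_points(soil) == 0L) stop("soil cloud is empty")
  structure(c(x = mean(plant$positions[, 1]),
              y = mean(plant$positions[, 2]),
              z = mean(soil$positions[, 3])),
            class = "root_point")
}

# distances from cloud points to the root (3D)
root_distances <- function(positions, root) {
  sqrt((positions[, 1] - root[1])^2 + (positions[, 2] - root[2])^2 +
         (positions[, 3] - root[3])^2)
}

#' Single segmented leaf
#'
#' Wraps a leaf's points with its tip (the point farthest from the root,
#' ties broken by lowest index) and centroid.
#'
#' @param points a [point_cloud] with the leaf's points.
#' @param root the [estimate_root()] result the leaf geometry is anchored to.
#' @param label integer leaf label.
#' @param synthetic optional logical vector flagging completion-added points.
#' @return an object of class `leaf_cloud`.
#' @export
leaf_cloud <- function(points, root, label = 1L, synthetic = NULL) {
  if (n_points(points) == 0L) stop("leaf must have at least one point")
  d <- root_distances(points$positions, root)
  tip_index <- which.max(d)
  if (is.null(synthetic)) synthetic <- logical(n_points(points))
  structure(list(points = points,
                 tip = points$positions[tip_index, ],
                 tip_index = tip_index,
                 centroid = colMeans(points$positions),
                 label = as.integer(label),
                 synthetic = synthetic),
            class = "leaf_cloud")
}

#' @export
print.leaf_cloud <- function(x, ...) {
  cat(sprintf("<leaf_cloud> label %d, %d points (%d synthetic)\n",
              x$label, n_points(x$points), sum(x$synthetic)))
  invisible(x)
}

#' Segment single leaves from a plant cloud
#'
#' Re-applies color-based region growing with tightened spatial and color
#' thresholds (single leaves are spatially thinner and more uniform in
#' color than the whole plant) and wraps each cluster as a [leaf_cloud].
#'
#' @param plant colored plant [point_cloud].
#' @param root output of [estimate_root()].
#' @param config a [completion_config()].
#' @return list of [leaf_cloud]s (possibly empty), labeled 1, 2, ...
#' @export
segment_leaves <- function(plant, root, config = completion_config()) {
  clusters <- region_grow_color(plant,
                                spatial_radius = config$leaf_spatial_radius,
                                color_threshold = config$leaf_color_threshold,
                                min_cluster_size = config$leaf_min_cluster_size)
  lapply(seq_along(clusters), function(k)
    leaf_cloud(subset_cloud(plant, clusters[[k]]), root, label = k))
}

#' Select outer leaves for completion
#'
#' Inner leaves are barely occluded; completing them would inflate the leaf
#' area. A leaf is completed only when its centroid lies far from the root:
#' at least `fraction` times the maximum centroid-to-root horizontal
#' distance over all leaves.
#'
#' @param leaves list of [leaf_cloud]s.
#' @param root output of [estimate_root()].
#' @param fraction relative distance threshold in (0, 1].
#' @return logical vector, `TRUE` for leaves to complete.
#' @export
select_leaves_for_completion <- function(leaves, root, fraction = 0.5) {
  if (length(leaves) == 0L) stop("no leaves to select from")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  d <- vapply(leaves, function(lf)
    sqrt((lf$centroid[1] - root[1])^2 + (lf$centroid[2] - root[2])^2),
    numeric(1))
  d >= fraction * max(d)
}

#' Closest edge of a leaf toward the root
#'
#' Thresholds the point-to-root distances at `d_TH = d_min + var_mul *
#' sigma` to obtain the raw root-facing edge, then screens the raw edge by
#' azimuthal binning around the root (one root-nearest survivor per
#' occupied bin) so that no two retained edge points share a fill ray.
#'
#' @param leaf a [leaf_cloud].
#' @param root output of [estimate_root()].
#' @param config a [completion_config()].
#' @return list with `raw_indices` (all points within `d_TH`), `indices`
#'   (screened edge points), `d_min`, `sigma`, `d_th`.
#' @export
closest_edge <- function(leaf, root, config = completion_config()) {
  pos <- leaf$points$positions
  if (nrow(pos) == 0L) stop("leaf is empty")
  d <- root_distances(pos, root)
  d_min <- min(d)
  sigma <- if (length(d) < 2L) 0 else switch(config$sigma_mode,
    std = stats::sd(d),
    printed = sum(d) / (length(d) - 1))
  d_th <- d_min + config$var_mul * sigma
  raw <- which(d <= d_th + 1e-9)
  az <- atan2(pos[raw, 2] - root[2], pos[raw, 1] - root[1])
  bin <- pmin(config$angular_bins - 1L,
              floor((az + pi) / (2 * pi / config$angular_bins)))
  keep <- vapply(split(seq_along(raw), bin),
                 function(ii) raw[ii][which.min(d[raw[ii]])], integer(1))
  list(raw_indices = raw, indices = sort(unname(keep)),
       d_min = d_min, sigma = sigma, d_th = d_th)
}

# signed side of each point about the xy axis root -> tip:
# positive = left, negative = right, 0 = on the axis
axis_side <- function(positions, root, tip) {
  dx <- tip[1] - root[1]
  dy <- tip[2] - root[2]
  if (dx^2 + dy^2 < 1e-24) stop("degenerate symmetry axis: tip over root")
  dx * (positions[, 2] - root[2]) - dy * (positions[, 1] - root[1])
}

# perpendicular distance (xy) of points to the axis line root -> tip
axis_distance <- function(positions, root, tip) {
  abs(axis_side(positions, root, tip)) /
    sqrt((tip[1] - root[1])^2 + (tip[2] - root[2])^2)
}

#' Left/right symmetry ratio of a leaf
#'
#' The symmetry axis is the xy line from the root to the leaf tip. Points
#' are classed left or right by the sign of the 2D cross product of
#' (tip - root) with (p - root); points exactly on the line count on
#' neither side. The imbalance ratio is
#' `delta = 2 |n_left - n_right| / (n_left + n_right)`; a leaf with
#' `delta <= mu` is balanced (symmetric).
#'
#' @param leaf a [leaf_cloud] with at least 2 points.
#' @param root output of [estimate_root()].
#' @param mu symmetry threshold (default 0.23).
#' @return list with `delta`, `n_left`, `n_right`, `heavier_side`
#'   (`"left"`, `"right"` or `"balanced"`).
#' @export
symmetry_ratio <- function(leaf, root, mu = 0.23) {
  pos <- leaf$points$positions
  if (nrow(pos) < 2L) stop("leaf must have at least 2 points")
  s <- axis_side(pos, root, leaf$tip)
  n_left <- sum(s > 0)
  n_right <- sum(s < 0)
  delta <- if (n_left + n_right == 0L) 0 else
    2 * abs(n_left - n_right) / (n_left + n_right)
  heavier <- if (delta <= mu) "balanced" else
    if (n_left > n_right) "left" else "right"
  list(delta = delta, n_left = n_left, n_right = n_right,
       heavier_side = heavier)
}

#' Mirror points across the vertical symmetry plane of a leaf
#'
#' Reflects across the vertical plane containing the root, the tip and the
#' world Z axis. Heights are preserved; the operation is an involution and
#' an isometry.
#'
#' @param points a [point_cloud] or an n x 3 position matrix.
#' @param root output of [estimate_root()].
#' @param tip leaf tip coordinates (xy distinct from the root).
#' @return object of the same type as `points`, same order and cardinality.
#' @export
mirror_leaf <- function(points, root, tip) {
  pos <- if (inherits(points, "point_cloud")) points$positions else
    matrix(as.numeric(points), ncol = 3)
  dx <- tip[1] - root[1]
  dy <- tip[2] - root[2]
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm < 1e-12) stop("degenerate symmetry axis: tip over root")
  nx <- -dy / nrm
  ny <- dx / nrm
  s <- (pos[, 1] - root[1]) * nx + (pos[, 2] - root[2]) * ny
  out <- pos
  out[, 1] <- pos[, 1] - 2 * s * nx
  out[, 2] <- pos[, 2] - 2 * s * ny
  if (inherits(points, "point_cloud"))
    point_cloud(out, colors = points$colors, frame = points$frame)
  else out
}

#' Trace the hole boundary along one side of a leaf
#'
#' Implements the ordered march along the inner rim of a half leaf: the
#' start point is, among the `n_s` points closest to the root, the one
#' closest (perpendicular xy distance) to the symmetry axis; each step
#' gathers the points within `search_radius` of the current point, drops
#' those not strictly farther from the root, and advances to the candidate
#' closest to the axis, until no candidate remains.
#'
#' @param side_points [point_cloud] or position matrix holding the points of
#'   one side of the symmetry axis.
#' @param root output of [estimate_root()].
#' @param tip leaf tip coordinates.
#' @param config a [completion_config()] with `search_radius` resolved.
#' @return list with `indices` (into `side_points`, boundary order) and
#'   `points` (the boundary coordinates, start point first).
#' @export
find_hole_boundary <- function(side_points, root, tip, config) {
  pos <- if (inherits(side_points, "point_cloud")) side_points$positions else
    matrix(as.numeric(side_points), ncol = 3)
  if (nrow(pos) == 0L) stop("side point set is empty")
  r <- config$search_radius
  if (is.na(r)) stop("search_radius must be resolved before boundary search")
  d_root <- root_distances(pos, root)
  d_axis <- axis_distance(pos, root, tip)
  near <- order(d_root)[seq_len(min(config$n_s, nrow(pos)))]
  cur <- near[which.min(d_axis[near])]
  boundary <- cur
  repeat {
    dd <- sqrt((pos[, 1] - pos[cur, 1])^2 + (pos[, 2] - pos[cur, 2])^2 +
                 (pos[, 3] - pos[cur, 3])^2)
    cand <- which(dd <= r & d_root > d_root[cur])
    if (length(cand) == 0L) break
    cur <- cand[which.min(d_axis[cand])]
    boundary <- c(boundary, cur)
  }
  list(indices = boundary, points = pos[boundary, , drop = FALSE])
}

#' Uniformly sample interior points of a segment
#'
#' Returns the `n = ceiling(|a - b| / spacing) - 1` arithmetic interior
#' points `a + k (b - a) / (n + 1)`, `k = 1..n`; the endpoints themselves
#' are excluded and the result is empty when `|a - b| <= spacing`.
#'
#' @param a,b segment endpoints (length-3 numeric).
#' @param spacing target spacing (m), > 0.
#' @return a [point_cloud] (world frame, no colors), possibly empty.
#' @export
fill_uniform <- function(a, b, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single value > 0")
  a <- as.numeric(a)[1:3]
  b <- as.numeric(b)[1:3]
  len <- sqrt(sum((b - a)^2))
  n <- ceiling(len / spacing) - 1
  if (n < 1) return(point_cloud(matrix(numeric(0), 0, 3), frame = "world"))
  k <- seq_len(n) / (n + 1)
  point_cloud(cbind(a[1] + k * (b[1] - a[1]),
                    a[2] + k * (b[2] - a[2]),
                    a[3] + k * (b[3] - a[3])), frame = "world")
}

#' Complete a single occluded leaf
#'
#' If the leaf is asymmetric (`delta > mu`), the heavier side is mirrored
#' across the root-tip plane and added, and the hole boundary of the heavier
#' side is traced; uniform fill is run between each boundary point and its
#' mirror image. In all cases the closest edge of the (augmented) leaf is
#' screened and uniform fill is run between each surviving edge point and
#' the root. All original points are retained; added points are flagged
#' synthetic and inherit the color of the nearest original leaf point.
#'
#' @param leaf a [leaf_cloud].
#' @param root output of [estimate_root()].
#' @param config a [completion_config()]; `fill_spacing`/`search_radius`
#'   resolve against the leaf itself when still `NA`.
#' @return the completed [leaf_cloud]; element `symmetry` carries the
#'   pre-completion [symmetry_ratio()] result.
#' @export
complete_leaf <- function(leaf, root, config = completion_config()) {
  config <- resolve_completion_config(config, leaf$points)
  orig <- leaf$points
  n_orig <- n_points(orig)
  sym <- symmetry_ratio(leaf, root, config$mu)
  added <- list()

  # Added points that land on (or hug) surface that is already sampled
  # duplicate it at a small vertical offset; such near-coincident double
  # layers would defeat the empty-ball test when the leaf is meshed, so
  # synthetic points within one fill spacing of an original point are
  # dropped (this also covers on-axis mirror images, which coincide with
  # their source exactly).
  prune <- function(pts) {
    if (is.null(pts) || nrow(pts) == 0L) return(NULL)
    nn <- cpp_nearest_index(pts, orig$positions)
    d <- sqrt(rowSums((pts - orig$positions[nn, , drop = FALSE])^2))
    keep <- d > 0.9 * config$fill_spacing
    if (!any(keep)) return(NULL)
    pts[keep, , drop = FALSE]
  }

  if (sym$delta > config$mu) {
    side <- axis_side(orig$positions, root, leaf$tip)
    heavy_idx <- if (sym$heavier_side == "left") which(side > 0) else
      which(side < 0)
    heavy <- orig$positions[heavy_idx, , drop = FALSE]
    mirrored <- prune(mirror_leaf(heavy, root, leaf$tip))
    if (!is.null(mirrored)) added <- c(added, list(mirrored))
    hb <- find_hole_boundary(heavy, root, leaf$tip, config)
    mirror_pts <- mirror_leaf(hb$points, root, leaf$tip)
    for (i in seq_len(nrow(hb$points))) {
      f <- fill_uniform(hb$points[i, ], mirror_pts[i, ], config$fill_spacing)
      if (n_points(f) > 0) {
        f <- prune(f$positions)
        if (!is.null(f)) added <- c(added, list(f))
      }
    }
  }

  aug_pos <- if (length(added)) rbind(orig$positions, do.call(rbind, added))
    else orig$positions
  aug_leaf <- leaf_cloud(point_cloud(aug_pos, frame = orig$frame), root,
                         label = leaf$label)
  edge <- closest_edge(aug_leaf, root, config)
  for (i in edge$indices) {
    f <- fill_uniform(aug_pos[i, ], root[1:3], config$fill_spacing)
    if (n_points(f) > 0) {
      f <- prune(f$positions)
      if (!is.null(f)) added <- c(added, list(f))
    }
  }

  if (length(added) == 0L)
    return(leaf_cloud(orig, root, label = leaf$label,
                      synthetic = logical(n_orig)))
  new_pos <- do.call(rbind, added)
  cols <- NULL
  if (has_colors(orig)) {
    nn <- cpp_nearest_index(new_pos, orig$positions)
    cols <- rbind(orig$colors, orig$colors[nn, , drop = FALSE])
  }
  out <- leaf_cloud(point_cloud(rbind(orig$positions, new_pos), colors = cols,
                                frame = orig$frame),
                    root, label = leaf$label,
                    synthetic = c(logical(n_orig),
                                  rep(TRUE, nrow(new_pos))))
  out$symmetry <- sym
  out
}

#' Complete a whole plant point cloud
#'
#' Orchestrates the pipeline on a segmented plant: estimate the root,
#' segment single leaves, select the outer leaves, complete each selected
#' leaf, merge everything back (all original points are retained,
#' completion is purely additive) and downsample the merged cloud at
#' `final_downsample_radius` to undo the repeated sampling that completion
#' introduces.
#'
#' @param plant colored plant [point_cloud] (world frame).
#' @param soil soil [point_cloud].
#' @param config a [completion_config()].
#' @return the completed, downsampled [point_cloud]. Attributes: `root`,
#'   `synthetic` (logical per output point), `leaf_labels` (integer per
#'   output point, 0 = not in any leaf cluster), `leaf_info` (data frame
#'   with per-leaf delta before/after and selection flags) and `config`
#'   (the resolved configuration).
#' @export
complete_plant <- function(plant, soil, config = completion_config()) {
  config <- resolve_completion_config(config, plant)
  root <- estimate_root(plant, soil)
  leaves <- segment_leaves(plant, root, config)

  finalize <- function(pos, cols, synth, labels, info) {
    merged <- point_cloud(pos, colors = cols, frame = plant$frame)
    # completion duplicates sampling within a leaf's own surface, so the
    # cull runs per leaf group: a synthetic point must never be dropped
    # just because a *different* leaf passes nearby, or the per-leaf
    # meshes end up with holes
    keep <- sort(unlist(lapply(split(seq_along(labels), labels), function(g)
      g[cpp_radius_downsample(merged$positions[g, , drop = FALSE],
                              config$final_downsample_radius)])))
    out <- subset_cloud(merged, keep)
    attr(out, "root") <- root
    attr(out, "synthetic") <- synth[keep]
    attr(out, "leaf_labels") <- labels[keep]
    attr(out, "leaf_info") <- info
    attr(out, "config") <- config
    out
  }

  if (length(leaves) == 0L)
    return(finalize(plant$positions, plant$colors,
                    logical(n_points(plant)), integer(n_points(plant)),
                    NULL))

  selected <- select_leaves_for_completion(leaves, root,
                                           config$completion_distance_fraction)
  # original points first (all of them), synthetic additions after
  add_pos <- list()
  add_col <- list()
  add_lab <- list()
  info <- data.frame(label = vapply(leaves, function(l) l$label, integer(1)),
                     n_points = vapply(leaves, function(l) n_points(l$points),
                                       integer(1)),
                     selected = selected,
                     delta_before = NA_real_, delta_after = NA_real_)
  completed <- vector("list", length(leaves))
  for (k in seq_along(leaves)) {
    if (!selected[k]) next
    cl <- complete_leaf(leaves[[k]], root, config)
    completed[[k]] <- cl
    info$delta_before[k] <- (cl$symmetry %||%
                               symmetry_ratio(leaves[[k]], root,
                                              config$mu))$delta
    if (any(cl$synthetic)) {
      pos <- cl$points$positions[cl$synthetic, , drop = FALSE]
      add_pos <- c(add_pos, list(pos))
      if (has_colors(plant))
        add_col <- c(add_col, list(cl$points$colors[cl$synthetic, ,
                                                    drop = FALSE]))
      add_lab <- c(add_lab, list(rep(leaves[[k]]$label, nrow(pos))))
    }
  }

  labels0 <- integer(n_points(plant))
  for (lf in leaves) {
    # recover each leaf's indices in the plant cloud by nearest identity
    idx <- cpp_nearest_index(lf$points$positions, plant$positions)
    labels0[idx] <- lf$label
  }
  pos <- rbind(plant$positions,
               if (length(add_pos)) do.call(rbind, add_pos))
  cols <- if (has_colors(plant))
    rbind(plant$colors, if (length(add_col)) do.call(rbind, add_col))
  synth <- c(logical(n_points(plant)),
             rep(TRUE, sum(vapply(add_pos, nrow, integer(1)))))
  labels <- c(labels0, unlist(add_lab) %||% integer(0))

  out <- finalize(pos, cols, synth, labels, info)

  # post-completion symmetry, measured on the pipeline's actual output
  # about each leaf's established root-tip axis (synthetic points must not
  # redefine the midrib the leaf was symmetrized on)
  out_labels <- attr(out, "leaf_labels")
  for (k in seq_along(leaves)) {
    if (!selected[k]) next
    idx <- which(out_labels == leaves[[k]]$label)
    if (length(idx) >= 2L) {
      lf <- leaf_cloud(subset_cloud(out, idx), root,
                       label = leaves[[k]]$label)
      lf$tip <- leaves[[k]]$tip
      info$delta_after[k] <- symmetry_ratio(lf, root, config$mu)$delta
    }
  }
  attr(out, "leaf_info") <- info
  out
}

#' Export a completed leaf or plant cloud with its synthetic flags
#'
#' Writes the cloud as ASCII PLY next to a sidecar CSV (`index`,
#' `synthetic`) flagging which points completion added — handy for
#' inspecting a repair in an external viewer.
#'
#' @param cloud a completed [leaf_cloud], or a [point_cloud] carrying a
#'   `synthetic` attribute (the output of [complete_plant()]).
#' @param path_prefix output stem; writes `<stem>.ply` and
#'   `<stem>_synthetic.csv`.
#' @return the two paths, invisibly.
#' @export
export_completed_cloud <- function(cloud, path_prefix) {
  if (inherits(cloud, "leaf_cloud")) {
    synth <- cloud$synthetic
    cloud <- cloud$points
  } else {
    synth <- attr(cloud, "synthetic") %||% logical(n_points(cloud))
  }
  ply <- paste0(path_prefix, ".ply")
  csv <- paste0(path_prefix, "_synthetic.csv")
  write_point_cloud(cloud, ply)
  utils::write.csv(data.frame(index = seq_len(n_points(cloud)),
                              synthetic = as.integer(synth)),
                   csv, row.names = FALSE)
  invisible(c(ply, csv))
}
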