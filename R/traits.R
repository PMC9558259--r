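#' Traits configuration
#'
#' @param cell_size occupancy-grid cell edge for the projected area (m);
#'   each occupied cell contributes `cell_size^2` (the per-point area
#'   proportion of the projection formula).
#' @param max_edge longest admissible triangle edge for surface
#'   triangulation (m); `NA` resolves to 1.5 x the cloud's sampling pitch
#'   ([point_pitch()]), which must bridge the sampling lattice diagonal.
#' @param pot_edge_z height of the fixed pot edge (m), the bottom reference
#'   of the relative height.
#' @param triangulation_k nearest-neighborhood size for triangle candidate
#'   generation.
#' @param normal_max_dev_deg cleanup threshold: triangles whose normal
#'   deviates from the local average by more than this are dropped.
#' @return an object of class `traits_config`.
#' @export
traits_config <- function(cell_size = 0.003, max_edge = NA_real_,
                          pot_edge_z = 0, triangulation_k = 15,
                          normal_max_dev_deg = 75) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (!is.na(max_edge) && max_edge <= 0) stop("max_edge must be > 0")
  structure(list(cell_size = cell_size, max_edge = max_edge,
                 pot_edge_z = pot_edge_z,
                 triangulation_k = as.integer(triangulation_k),
                 normal_max_dev_deg = normal_max_dev_deg),
            class = "traits_config")
}

#' Absolute and relative plant height
#'
#' `H_abs = H_top - H_soil` (top of the plant above the mean soil height)
#' and `H_rel = H_top - pot_edge_z` (top above the fixed pot edge, the part
#' of the plant a top view can actually see).
#'
#' @param plant non-empty plant [point_cloud] (world frame, Z up).
#' @param soil soil [point_cloud]; required for `H_abs`.
#' @param config a [traits_config()].
#' @return list with `H_abs` and `H_rel` in meters.
#' @export
estimate_heights <- function(plant, soil, config = traits_config()) {
  if (n_points(plant) == 0L) stop("plant cloud is empty")
  if (n_points(soil) == 0L) stop("soil cloud is empty (needed for H_abs)")
  h_top <- max(plant$positions[, 3])
  list(H_abs = h_top - mean(soil$positions[, 3]),
       H_rel = h_top - config$pot_edge_z)
}

#' Projected (canopy) area by grid occupancy
#'
#' Points are projected to the xy plane and binned into a square grid of
#' edge `cell_size` anchored at the cloud's min corner (half-open cells);
#' the projected area is the occupied-cell count times `cell_size^2`, i.e.
#' the down-sampled point count times the per-point area proportion.
#'
#' @param cloud non-empty [point_cloud].
#' @param cell_size grid cell edge (m), > 0.
#' @return projected area in m^2.
#' @export
projected_area <- function(cloud, cell_size = 0.003) {
  if (n_points(cloud) == 0L) stop("cloud is empty")
  if (cell_size <= 0) stop("cell_size must be > 0")
  p <- cloud$positions
  ix <- floor((p[, 1] - min(p[, 1])) / cell_size)
  iy <- floor((p[, 2] - min(p[, 2])) / cell_size)
  n_occ <- length(unique(complex(real = ix, imaginary = iy)))
  n_occ * cell_size^2
}

#' Greedy Gabriel-style surface triangulation
#'
#' Candidate triangles are triples within each point's nearest
#' neighborhood whose edges are all at most `max_edge` and whose minimum
#' enclosing ball (circumball for acute triangles, longest-edge diametral
#' ball otherwise) contains no other point strictly inside. Candidates are
#' accepted greedily by increasing ball radius; a candidate is rejected
#' when an edge would exceed two incident triangles or would properly cross
#' an accepted edge, which removes redundant overlapping patches and keeps
#' the mesh two-manifold-like. Two cleanup passes follow: suspended
#' triangles (sharing no edge with any other, when edge-sharing pairs
#' exist) and triangles whose normal deviates more than
#' `normal_max_dev_deg` from the local average are dropped.
#'
#' @param cloud a [point_cloud] with at least 3 points.
#' @param max_edge longest admissible edge (m); `NA` resolves to 1.5 x the
#'   sampling pitch ([point_pitch()]).
#' @param config a [traits_config()] (neighborhood size, normal threshold).
#' @return an object of class `triangle_mesh`: list with `vertices`
#'   (n x 3) and `triangles` (m x 3 vertex indices).
#' @export
triangulate <- function(cloud, max_edge = NA_real_,
                        config = traits_config()) {
  if (n_points(cloud) < 3L) stop("need at least 3 points to triangulate")
  if (is.na(max_edge)) max_edge <- config$max_edge
  if (is.na(max_edge)) max_edge <- 1.5 * point_pitch(cloud)
  tri <- cpp_triangulate(cloud$positions, max_edge, config$triangulation_k)
  mesh <- structure(list(vertices = cloud$positions, triangles = tri),
                    class = "triangle_mesh")
  mesh <- drop_suspended(mesh)
  drop_deviant_normals(mesh, config$normal_max_dev_deg)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles, area %.6g m^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

triangle_normals <- function(mesh) {
  v <- mesh$vertices
  t1 <- mesh$triangles[, 1]
  t2 <- mesh$triangles[, 2]
  t3 <- mesh$triangles[, 3]
  e1 <- v[t2, , drop = FALSE] - v[t1, , drop = FALSE]
  e2 <- v[t3, , drop = FALSE] - v[t1, , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n <- n / pmax(len, 1e-300)
  flip <- n[, 3] < 0  # orient upward: one-sided top-view surfaces
  n[flip, ] <- -n[flip, , drop = FALSE]
  n
}

edge_keys <- function(mesh) {
  t <- mesh$triangles
  nv <- nrow(mesh$vertices)
  a <- cbind(t[, 1], t[, 1], t[, 2])
  b <- cbind(t[, 2], t[, 3], t[, 3])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  matrix(as.numeric(lo) * (nv + 1) + as.numeric(hi), ncol = 3)
}

drop_suspended <- function(mesh) {
  m <- nrow(mesh$triangles)
  if (m < 2L) return(mesh)
  ek <- edge_keys(mesh)
  cnt <- table(as.numeric(ek))
  shared <- matrix(cnt[as.character(as.numeric(ek))] > 1, ncol = 3)
  connected <- rowSums(shared) > 0
  if (!any(connected)) return(mesh)  # no edge-sharing pair anywhere: keep
  mesh$triangles <- mesh$triangles[connected, , drop = FALSE]
  mesh
}

drop_deviant_normals <- function(mesh, max_dev_deg) {
  m <- nrow(mesh$triangles)
  if (m < 2L) return(mesh)
  nrm <- triangle_normals(mesh)
  nv <- nrow(mesh$vertices)
  # accumulate per-vertex normal sums
  vsum <- matrix(0, nv, 3)
  for (j in 1:3) {
    idx <- mesh$triangles[, j]
    for (d in 1:3) {
      s <- rowsum(nrm[, d], idx)
      vsum[as.integer(rownames(s)), d] <- vsum[as.integer(rownames(s)), d] + s
    }
  }
  local <- vsum[mesh$triangles[, 1], , drop = FALSE] +
    vsum[mesh$triangles[, 2], , drop = FALSE] +
    vsum[mesh$triangles[, 3], , drop = FALSE]
  llen <- sqrt(rowSums(local^2))
  cosang <- abs(rowSums(nrm * local)) / pmax(llen, 1e-300)
  keep <- llen < 1e-12 | cosang >= cos(max_dev_deg * pi / 180)
  mesh$triangles <- mesh$triangles[keep, , drop = FALSE]
  mesh
}

#' Total area of a triangle mesh
#'
#' Sum over triangles of half the cross-product magnitude; an empty mesh
#' has area 0.
#'
#' @param mesh a `triangle_mesh`.
#' @return area in m^2.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(0)
  v <- mesh$vertices
  t1 <- mesh$triangles[, 1]
  t2 <- mesh$triangles[, 2]
  t3 <- mesh$triangles[, 3]
  e1 <- v[t2, , drop = FALSE] - v[t1, , drop = FALSE]
  e2 <- v[t3, , drop = FALSE] - v[t1, , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Total leaf area of a labeled plant cloud
#'
#' Triangulates each leaf separately and sums the mesh areas. Meshing
#' leaves one at a time matters for completed clouds: completion restores
#' occluded layers underneath other leaves, and the empty-ball acceptance
#' test would otherwise discard triangles wherever another leaf's surface
#' passes nearby. Points with label 0 (not in any leaf cluster) are meshed
#' together as a remainder group.
#'
#' @param cloud a [point_cloud], e.g. the output of [complete_plant()].
#' @param labels integer per-point leaf labels (0 = unassigned); defaults
#'   to the `leaf_labels` attribute left by [complete_plant()].
#' @param config a [traits_config()].
#' @return total area in m^2.
#' @export
total_leaf_area <- function(cloud, labels = NULL, config = traits_config()) {
  if (is.null(labels)) labels <- attr(cloud, "leaf_labels")
  if (is.null(labels)) return(mesh_area(triangulate(cloud, config$max_edge,
                                                    config)))
  if (length(labels) != n_points(cloud)) stop("one label per point required")
  total <- 0
  for (idx in split(seq_along(labels), labels)) {
    if (length(idx) < 3L) next
    total <- total + mesh_area(triangulate(subset_cloud(cloud, idx),
                                           config$max_edge, config))
  }
  total
}

#' Write a mesh to PLY or OBJ
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param format `"ply"` (ASCII, with face element) or `"obj"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "obj")) {
  format <- match.arg(format)
  v <- mesh$vertices
  t <- mesh$triangles
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property float x", "property float y", "property float z",
             paste("element face", nrow(t)),
             "property list uchar int vertex_indices", "end_header")
    vb <- apply(matrix(sprintf("%.9g", t(v)), nrow = 3), 2, paste,
                collapse = " ")
    fb <- paste(3, t[, 1] - 1, t[, 2] - 1, t[, 3] - 1)
    writeLines(c(hdr, vb, fb), path)
  } else {
    vb <- paste("v", sprintf("%.9g", v[, 1]), sprintf("%.9g", v[, 2]),
                sprintf("%.9g", v[, 3]))
    fb <- paste("f", t[, 1], t[, 2], t[, 3])
    writeLines(c(vb, fb), path)
  }
  invisible(path)
}

#' Fit an allometric model from total leaf area
#'
#' Whole-plant volume and fresh weight scale linearly with total leaf area
#' in rosette plants, so a calibrated ordinary least-squares line predicts
#' them from the triangulated area. Predictions are clamped below at 0.
#'
#' @param areas total leaf areas (m^2), at least 2 distinct values.
#' @param responses measured responses (g or mL), same length.
#' @param response_name `"weight_g"` or `"volume_mL"`.
#' @return an object of class `allometric_model` with `slope`, `intercept`,
#'   `r_squared`, `response_name` and `degenerate` (TRUE when the responses
#'   had no variance, in which case `r_squared` is 1 by convention).
#' @export
fit_allometry <- function(areas, responses,
                          response_name = c("weight_g", "volume_mL")) {
  response_name <- match.arg(response_name)
  if (length(areas) != length(responses)) stop("length mismatch")
  if (length(areas) < 2L) stop("need at least 2 calibration points")
  if (stats::var(areas) == 0) stop("areas must not all be equal")
  fit <- stats::lm(responses ~ areas)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  degenerate <- ss_tot == 0
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (degenerate) 1 else 1 - ss_res / ss_tot,
                 response_name = response_name,
                 degenerate = degenerate),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("<allometric_model> %s = %.4g * area + %.4g (R^2 = %.3f)%s\n",
              x$response_name, x$slope, x$intercept, x$r_squared,
              if (x$degenerate) " [degenerate: constant response]" else ""))
  invisible(x)
}

#' Predict volume or weight from total leaf area
#'
#' @param model an [fit_allometry()] model.
#' @param area total leaf area(s) in m^2.
#' @return predicted response, clamped below at 0.
#' @export
predict_allometry <- function(model, area) {
  pmax(0, model$slope * area + model$intercept)
}
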