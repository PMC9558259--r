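#' Synthetic rosette scene specification
#'
#' Describes a rosette plant (leaves radiating from a central root crown
#' over a flat soil disc) as seen by a top-view sensor. Each leaf is a
#' sampled parametric open surface: the midrib runs radially outward from
#' `inner_gap`, rising at `inclination` and bending down with `droop`; the
#' lamina extends laterally with an elliptic half-width profile peaking at
#' `width_ratio` times the leaf length. Per-leaf variation (length, lift,
#' base height, hue) makes neighboring leaves overlap near the crown, which
#' is what the z-buffer occlusion then deletes.
#'
#' @param n_leaves number of leaves (>= 1).
#' @param leaf_length_mean,leaf_length_sd horizontal midrib run (m).
#' @param width_ratio max lamina half-width / leaf length.
#' @param inclination midrib lift from horizontal (radians).
#' @param droop downward curvature of the midrib (1/m).
#' @param inner_gap radial gap between root and leaf surface start (m); the
#'   zone the completion fills.
#' @param asymmetry fraction of one lateral half removed from the visible
#'   cloud of every other leaf, in [0, 1); emulates one-sided occlusion.
#' @param point_spacing target sample spacing on surfaces (m).
#' @param soil_radius radius of the soil disc (m).
#' @param seed integer seed; scenes are bit-identical given the same spec.
#' @param root_occlusion_range per-leaf range of the root-side occlusion:
#'   each leaf loses the visible points over the innermost fraction of its
#'   span, the fraction drawn uniformly from this range. This is the
#'   deletion near the root that the emerging crown foliage casts on every
#'   outer leaf of a rosette seen from above --- the structure the
#'   completion algorithm assumes and repairs.
#' @param base_height_range per-leaf crown height range (m); kept tight,
#'   as leaves of one whorl emerge from the same crown.
#' @param inclination_jitter per-leaf lift jitter (radians). Kept small:
#'   rosette leaves arrange themselves into the gaps left by their
#'   neighbors to maximize light capture, so same-whorl laminae are nearly
#'   co-inclined and mutual mid-leaf shading is second-order; the
#'   first-order occlusion is the crown shade near the root.
#' @param leaf_color_jitter radius of the per-leaf hue wheel around the
#'   green base (60, 160, 70): leaf i gets a red/blue offset of this
#'   magnitude at angle `2 pi (i - 1) / n_leaves` plus a random scene
#'   phase. Evenly spaced hues emulate the per-leaf color differences
#'   (age, illumination) that color-based segmentation exploits, while
#'   keeping distinct leaves separable by construction.
#' @param point_color_jitter per-point RGB jitter.
#' @param occlusion_cell,occlusion_depth_tol z-buffer cell edge and depth
#'   tolerance used for the visible cloud (m). The tolerance must cover
#'   the depth span of a tilted lamina within one cell (`cell *
#'   tan(steepest lift)`), or the buffer deletes points of the very
#'   surface it should keep; 4 mm covers lifts to ~53 degrees at 3 mm
#'   cells.
#' @return an object of class `rosette_spec`.
#' @export
rosette_spec <- function(n_leaves = 10, leaf_length_mean = 0.10,
                         leaf_length_sd = 0.015, width_ratio = 0.28,
                         inclination = 30 * pi / 180, droop = 1.0,
                         inner_gap = 0.012, asymmetry = 0,
                         point_spacing = 0.003, soil_radius = 0.12,
                         seed = 1L,
                         root_occlusion_range = c(0.15, 0.35),
                         base_height_range = c(0.001, 0.002),
                         inclination_jitter = 0.5 * pi / 180,
                         leaf_color_jitter = 55, point_color_jitter = 3,
                         occlusion_cell = 0.003,
                         occlusion_depth_tol = 0.004) {
  if (n_leaves < 1) stop("n_leaves must be >= 1")
  if (leaf_length_mean <= 0 || width_ratio <= 0 || inner_gap <= 0 ||
      point_spacing <= 0 || soil_radius <= 0)
    stop("all lengths must be > 0")
  if (asymmetry < 0 || asymmetry >= 1) stop("asymmetry must lie in [0, 1)")
  structure(list(n_leaves = as.integer(n_leaves),
                 leaf_length_mean = leaf_length_mean,
                 leaf_length_sd = leaf_length_sd,
                 width_ratio = width_ratio, inclination = inclination,
                 droop = droop, inner_gap = inner_gap, asymmetry = asymmetry,
                 point_spacing = point_spacing, soil_radius = soil_radius,
                 seed = as.integer(seed),
                 root_occlusion_range = root_occlusion_range,
                 base_height_range = base_height_range,
                 inclination_jitter = inclination_jitter,
                 leaf_color_jitter = leaf_color_jitter,
                 point_color_jitter = point_color_jitter,
                 occlusion_cell = occlusion_cell,
                 occlusion_depth_tol = occlusion_depth_tol),
            class = "rosette_spec")
}

# clamp a numeric matrix into valid color channels, keeping its shape
clamp255 <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

# lamina half-width at relative midrib position u in [0, 1]
lamina_half_width <- function(u, length, width_ratio) {
  width_ratio * length * sqrt(pmax(0, 1 - (2 * u - 1)^2))
}

# surface area of one leaf: for this ruled lamina the exact area is
# integral of 2 w(s) sqrt(1 + z'(s)^2) ds, evaluated by fine quadrature
leaf_surface_area <- function(length, width_ratio, incl, droop, step) {
  s <- seq(0, length, by = step)
  zp <- tan(incl) - 2 * droop * s
  w <- lamina_half_width(s / length, length, width_ratio)
  f <- 2 * w * sqrt(1 + zp^2)
  sum((f[-1] + f[-length(f)]) / 2 * diff(s))
}

#' Generate a synthetic rosette scene
#'
#' Builds the labeled full point cloud (soil disc plus leaves), the
#' analytic per-leaf and scene truths, and the visible cloud after z-buffer
#' occlusion (plus the one-sided sector deletion when `asymmetry > 0`).
#' Deterministic given the spec's seed.
#'
#' @param spec a [rosette_spec()].
#' @return an object of class `synthetic_scene`: list with `full`
#'   ([point_cloud]), `visible` ([point_cloud], a subset of `full`),
#'   `labels_full` / `labels_visible` (integer per point, 0 = soil, k =
#'   leaf k), and `truth` (list: `leaf_areas`, `total_area`, `projected_area`,
#'   `H_abs`, `H_rel`, `root`, all in meters/m^2).
#' @export
generate_rosette <- function(spec) {
  if (!inherits(spec, "rosette_spec")) stop("spec must be a rosette_spec")
  with_seed(spec$seed, {
    sp <- spec$point_spacing
    gap_az <- 2 * pi / spec$n_leaves
    hue_phase <- stats::runif(1, 0, 2 * pi)
    pos <- list(); col <- list(); lab <- list(); asym_flag <- list()
    leaf_areas <- numeric(spec$n_leaves)

    for (i in seq_len(spec$n_leaves)) {
      len <- max(0.03, stats::rnorm(1, spec$leaf_length_mean,
                                    spec$leaf_length_sd))
      az <- (i - 1) * gap_az + stats::runif(1, -0.05, 0.05) * gap_az
      incl <- spec$inclination +
        stats::runif(1, -1, 1) * spec$inclination_jitter
      drp <- spec$droop * stats::runif(1, 0.95, 1.05)
      h0 <- stats::runif(1, spec$base_height_range[1],
                         spec$base_height_range[2])
      leaf_areas[i] <- leaf_surface_area(len, spec$width_ratio, incl, drp,
                                         sp / 4)

      # midrib stations at ~point_spacing arc length
      s_fine <- seq(0, len, by = sp / 8)
      arc <- cumsum(c(0, diff(s_fine) *
                        sqrt(1 + (tan(incl) - 2 * drp * s_fine[-1])^2)))
      s_st <- stats::approx(arc, s_fine,
                            xout = unique(c(seq(0, max(arc), by = sp),
                                            max(arc))))$y
      dirx <- cos(az); diry <- sin(az)
      px <- c(); py <- c(); pz <- c(); pt <- c()
      for (s in s_st) {
        w <- lamina_half_width(s / len, len, spec$width_ratio)
        t_in <- if (w >= sp) as.vector(outer(seq_len(floor(w / sp)),
                                             c(-1, 1))) * sp else numeric(0)
        # sample the rim itself so the cloud spans the full lamina width
        t_rim <- if (w > 0.25 * sp && w - max(0, t_in) > 0.25 * sp)
          c(-w, w) else numeric(0)
        t_off <- c(0, t_in, t_rim)
        r <- spec$inner_gap + s
        z <- max(5e-4, h0 + s * tan(incl) - drp * s^2)
        px <- c(px, r * dirx - t_off * diry)
        py <- c(py, r * diry + t_off * dirx)
        pz <- c(pz, rep(z, length(t_off)))
        pt <- c(pt, t_off)
      }
      n_i <- length(px)
      beta <- hue_phase + (i - 1) * gap_az
      base_col <- pmin(255, pmax(0, c(60 + spec$leaf_color_jitter * cos(beta),
                                      160,
                                      70 + spec$leaf_color_jitter * sin(beta))))
      jit <- matrix(round(stats::runif(3 * n_i, -1, 1) *
                            spec$point_color_jitter), ncol = 3)
      ci <- clamp255(t(base_col + t(jit)))

      # occlusion sectors (removed from the visible cloud only):
      # every leaf loses its root-side portion under the crown foliage,
      # and every other leaf additionally loses one lateral flank sector
      srel <- (sqrt(px^2 + py^2) - spec$inner_gap) / len
      c_i <- stats::runif(1, spec$root_occlusion_range[1],
                          spec$root_occlusion_range[2])
      af <- srel < c_i
      if (spec$asymmetry > 0 && i %% 2 == 1) {
        u0 <- stats::runif(1, 0, 1 - spec$asymmetry)
        af <- af | (pt > 0 & srel >= u0 & srel <= u0 + spec$asymmetry)
      }
      pos[[i]] <- cbind(px, py, pz)
      col[[i]] <- ci
      lab[[i]] <- rep(i, n_i)
      asym_flag[[i]] <- af
    }

    # soil disc at z = 0
    g <- seq(-spec$soil_radius, spec$soil_radius, by = sp)
    soil_xy <- as.matrix(expand.grid(x = g, y = g))
    soil_xy <- soil_xy[soil_xy[, 1]^2 + soil_xy[, 2]^2 <= spec$soil_radius^2, ]
    n_s <- nrow(soil_xy)
    soil_col <- clamp255(t(c(135, 90, 65) +
      t(matrix(round(stats::runif(3 * n_s, -10, 10)), ncol = 3))))

    positions <- rbind(cbind(soil_xy, 0), do.call(rbind, pos))
    colors <- rbind(soil_col, do.call(rbind, col))
    labels <- c(rep(0L, n_s), unlist(lab))
    asym <- c(logical(n_s), unlist(asym_flag))
    full <- point_cloud(positions, colors = colors, frame = "world")

    keep <- cpp_zbuffer_keep(full$positions, spec$occlusion_cell,
                             spec$occlusion_depth_tol) & !asym
    visible <- subset_cloud(full, which(keep))

    plant_full <- subset_cloud(full, which(labels > 0))
    truth <- list(leaf_areas = leaf_areas, total_area = sum(leaf_areas),
                  projected_area = projected_area(plant_full,
                                                  spec$occlusion_cell),
                  H_abs = max(plant_full$positions[, 3]),
                  H_rel = max(plant_full$positions[, 3]),
                  root = c(0, 0, 0))

    structure(list(full = full, visible = visible,
                   labels_full = labels, labels_visible = labels[keep],
                   truth = truth, spec = spec),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scene> %d leaves, %d full / %d visible ",
                     "points, true total leaf area %.4f m^2\n"),
              x$spec$n_leaves, n_points(x$full), n_points(x$visible),
              x$truth$total_area))
  invisible(x)
}

#' Simulate a top-view sensor by z-buffer visibility
#'
#' Bins points into vertical xy cells and keeps, per cell, only the points
#' within `depth_tol` of the cell's highest point — what a single
#' downward-looking sensor can see.
#'
#' @param cloud a [point_cloud].
#' @param cell xy cell edge (m), > 0.
#' @param depth_tol depth tolerance below the cell top (m), >= 0.
#' @return the visible subset of `cloud` (original order).
#' @export
simulate_top_view <- function(cloud, cell = 0.003, depth_tol = 0.002) {
  if (cell <= 0) stop("cell must be > 0")
  if (depth_tol < 0) stop("depth_tol must be >= 0")
  if (n_points(cloud) == 0L) return(cloud)
  keep <- cpp_zbuffer_keep(cloud$positions, cell, depth_tol)
  subset_cloud(cloud, which(keep))
}

#' Standard synthetic benchmark scenes
#'
#' Draws `n_scenes` rosette scenes from documented ranges — 8-14 leaves,
#' mean leaf length 0.06-0.15 m, inclination 15-45 degrees, droop 0.5-2 per
#' meter — with the one-sided asymmetry alternating between 0 and 0.6 from
#' scene to scene. Scene i uses seed `base_seed + i`; parameter draws come
#' from a derived stream so the whole list is deterministic per
#' `(n_scenes, base_seed)`.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param base_seed integer base seed.
#' @return list of `synthetic_scene`s.
#' @export
standard_benchmark <- function(n_scenes = 20, base_seed = 1L) {
  if (n_scenes < 1) stop("n_scenes must be >= 1")
  lapply(seq_len(n_scenes), function(i) {
    spec <- with_seed((base_seed * 131L + 17L * i) %% 2147483647L, {
      rosette_spec(n_leaves = sample(8:14, 1),
                   leaf_length_mean = stats::runif(1, 0.06, 0.15),
                   leaf_length_sd = 0.12 * stats::runif(1, 0.06, 0.15),
                   inclination = stats::runif(1, 15, 45) * pi / 180,
                   droop = stats::runif(1, 0.5, 2),
                   asymmetry = if (i %% 2 == 0) 0 else 0.6,
                   seed = base_seed + i)
    })
    generate_rosette(spec)
  })
}

#' Export a synthetic scene to PLY files plus a JSON truth sidecar
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return paths of the written files, invisibly.
#' @export
export_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_full <- file.path(dir, paste0(name, "_full.ply"))
  p_vis <- file.path(dir, paste0(name, "_visible.ply"))
  p_truth <- file.path(dir, paste0(name, "_truth.json"))
  write_point_cloud(scene$full, p_full)
  write_point_cloud(scene$visible, p_vis)
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write the truth sidecar")
  jsonlite::write_json(scene$truth, p_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(p_full, p_vis, p_truth))
}
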