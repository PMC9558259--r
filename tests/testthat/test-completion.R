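test_that("root estimation uses plant centroid and mean soil height", {
  plant <- point_cloud(rbind(c(-1, 0, 1), c(1, 0, 1), c(0, -2, 2),
                             c(0, 2, 2)), frame = "world")
  soil <- point_cloud(rbind(c(5, 5, 0), c(6, 6, 0.01), c(7, 7, 0.02)),
                      frame = "world")
  root <- estimate_root(plant, soil)
  expect_equal(unname(root[1:2]), c(0, 0))
  expect_equal(unname(root[3]), 0.01)
  # translation equivariance
  t_ <- c(0.3, -0.2, 0.05)
  root2 <- estimate_root(
    point_cloud(t(t(plant$positions) + t_), frame = "world"),
    point_cloud(t(t(soil$positions) + t_), frame = "world"))
  expect_equal(unname(root2 - root), t_)
  expect_error(estimate_root(point_cloud(matrix(numeric(0), 0, 3)), soil),
               "empty")
})

test_that("leaf segmentation yields one labeled leaf per separated blob", {
  tp <- toy_plant(n_leaves = 4)
  root <- estimate_root(tp$plant, tp$soil)
  leaves <- segment_leaves(tp$plant, root,
                           completion_config(leaf_spatial_radius = 0.005,
                                             leaf_color_threshold = 15,
                                             leaf_min_cluster_size = 10))
  expect_length(leaves, 4)
  expect_identical(vapply(leaves, function(l) l$label, integer(1)), 1:4)
  # tip is the brute-force farthest point from the root
  for (lf in leaves) {
    d <- sqrt(colSums((t(lf$points$positions) - root[1:3])^2))
    expect_equal(unname(lf$tip), lf$points$positions[which.max(d), ])
    expect_equal(lf$centroid, colMeans(lf$points$positions))
  }
})

test_that("leaf tip ties break toward the lowest index", {
  pts <- point_cloud(rbind(c(0.01, 0, 0), c(0.05, 0, 0), c(-0.05, 0, 0)),
                     frame = "world")
  lf <- leaf_cloud(pts, structure(c(0, 0, 0), class = "root_point"))
  expect_equal(lf$tip_index, 2L)  # both extremes at 0.05; index 2 comes first
})

test_that("outer-leaf selection thresholds on relative centroid distance", {
  root <- structure(c(0, 0, 0), class = "root_point")
  mk <- function(d) leaf_cloud(point_cloud(rbind(c(d, 0, 0), c(d, 0.001, 0)),
                                           frame = "world"), root)
  leaves <- list(mk(0.10), mk(0.09), mk(0.02))
  expect_identical(select_leaves_for_completion(leaves, root, 0.5),
                   c(TRUE, TRUE, FALSE))
  expect_true(select_leaves_for_completion(leaves[1], root, 0.5))
  expect_identical(select_leaves_for_completion(leaves, root, 1.0),
                   c(TRUE, FALSE, FALSE))
})

test_that("closest-edge thresholding matches the brute-force oracle", {
  root <- structure(c(0, 0, 0), class = "root_point")
  set.seed(21)
  pos <- cbind(runif(200, 0.02, 0.1), runif(200, -0.02, 0.02),
               runif(200, 0, 0.03))
  lf <- leaf_cloud(point_cloud(pos, frame = "world"), root)
  for (vm in c(0, 1, 2)) {
    edge <- closest_edge(lf, root, completion_config(var_mul = vm))
    expect_identical(edge$raw_indices, oracle_edge_raw(pos, root, vm))
  }
  # var_mul = 0 degenerates to the d_min points
  e0 <- closest_edge(lf, root, completion_config(var_mul = 0))
  d <- sqrt(rowSums(pos^2))
  expect_identical(e0$raw_indices, which(d <= min(d) + 1e-9))
  # raw edge is monotone in var_mul
  e1 <- closest_edge(lf, root, completion_config(var_mul = 1))
  e2 <- closest_edge(lf, root, completion_config(var_mul = 2))
  expect_true(all(e1$raw_indices %in% e2$raw_indices))
  # printed-sigma variant uses the scaled distance sum
  ep <- closest_edge(lf, root, completion_config(var_mul = 1,
                                                 sigma_mode = "printed"))
  expect_equal(ep$sigma, sum(d) / (length(d) - 1))
  expect_identical(ep$raw_indices, oracle_edge_raw(pos, root, 1, "printed"))
})

test_that("edge screening keeps one root-nearest survivor per azimuth bin", {
  root <- structure(c(0, 0, 0), class = "root_point")
  set.seed(4)
  pos <- cbind(runif(300, 0.02, 0.08), runif(300, -0.03, 0.03), 0)
  lf <- leaf_cloud(point_cloud(pos, frame = "world"), root)
  cfg <- completion_config(var_mul = 2, angular_bins = 36)
  edge <- closest_edge(lf, root, cfg)
  az <- atan2(pos[edge$indices, 2], pos[edge$indices, 1])
  bins <- floor((az + pi) / (2 * pi / 36))
  expect_false(anyDuplicated(bins) > 0)
  expect_true(all(edge$indices %in% edge$raw_indices))
})

test_that("symmetry ratio counts sides by the 2D cross product", {
  root <- structure(c(0, 0, 0), class = "root_point")
  pos <- rbind(cbind(runif(60, 0.01, 0.09), runif(60, 1e-4, 0.03), 0),
               cbind(runif(40, 0.01, 0.09), runif(40, -0.03, -1e-4), 0),
               c(0.1, 0, 0))  # tip on the axis, counted on neither side
  lf <- leaf_cloud(point_cloud(pos, frame = "world"), root)
  s <- symmetry_ratio(lf, root)
  expect_equal(s$n_left, 60)
  expect_equal(s$n_right, 40)
  expect_equal(s$delta, 0.4)
  expect_equal(s$heavier_side, "left")
  # mirrored cloud keeps the same delta
  m <- mirror_leaf(lf$points, root, lf$tip)
  sm <- symmetry_ratio(leaf_cloud(m, root), root)
  expect_equal(sm$delta, s$delta)
  expect_equal(sm$heavier_side, "right")
  # balanced case
  bal <- leaf_cloud(point_cloud(rbind(c(0.05, 0.01, 0), c(0.05, -0.01, 0),
                                      c(0.09, 0, 0)), frame = "world"), root)
  sb <- symmetry_ratio(bal, root)
  expect_equal(sb$delta, 0)
  expect_equal(sb$heavier_side, "balanced")
  # degenerate axis
  deg <- leaf_cloud(point_cloud(rbind(c(0, 0, 0.05), c(0, 0, 0.02)),
                                frame = "world"), root)
  expect_error(symmetry_ratio(deg, root), "degenerate")
})

test_that("mirroring is a z-preserving involutive isometry", {
  root <- c(0, 0, 0)
  tip <- c(1, 0, 0)
  expect_equal(mirror_leaf(rbind(c(0.5, 0.2, 0.1)), root, tip),
               rbind(c(0.5, -0.2, 0.1)))
  expect_equal(mirror_leaf(rbind(c(0.3, 0, 0.7)), root, tip),
               rbind(c(0.3, 0, 0.7)))  # on-plane points are fixed
  set.seed(12)
  pts <- matrix(runif(90, -0.1, 0.1), ncol = 3)
  tip2 <- c(0.07, 0.03, 0.02)
  m <- mirror_leaf(pts, root, tip2)
  expect_equal(mirror_leaf(m, root, tip2), pts, tolerance = 1e-9)
  expect_equal(m[, 3], pts[, 3])
  expect_equal(dist_matrix(m), dist_matrix(pts), tolerance = 1e-9)
})

test_that("uniform fill places interior points at arithmetic positions", {
  f <- fill_uniform(c(0, 0, 0), c(1, 0, 0), 0.25)
  expect_equal(f$positions, cbind(c(0.25, 0.5, 0.75), 0, 0))
  expect_equal(n_points(fill_uniform(c(0, 0, 0), c(0.2, 0, 0), 0.25)), 0)
  a <- c(0.1, -0.2, 0.3)
  b <- c(-0.4, 0.5, 0.6)
  f2 <- fill_uniform(a, b, 0.07)$positions
  # collinear and strictly between the endpoints
  ab <- b - a
  tpar <- ((t(f2) - a)[1, ]) / ab[1]
  expect_true(all(tpar > 0 & tpar < 1))
  for (i in seq_len(nrow(f2)))
    expect_equal(unname(f2[i, ]), unname(a + tpar[i] * ab), tolerance = 1e-12)
  expect_error(fill_uniform(a, b, 0), "spacing")
})

test_that("hole-boundary search replays the exhaustive oracle", {
  root <- structure(c(0, 0, 0), class = "root_point")
  tip <- c(0.1, 0, 0)
  cfg <- completion_config(search_radius = 0.0046, fill_spacing = 0.003)
  # half grid beside the axis with a rectangular notch at the axis
  s <- 0.003
  g <- expand.grid(x = seq(s, 0.03, by = s), y = seq(s, 0.015, by = s))
  notch <- g$x >= 0.006 & g$x <= 0.015 & g$y <= 0.006
  pos <- cbind(g$x[!notch], g$y[!notch], 0)
  hb <- find_hole_boundary(pos, root, tip, cfg)
  expect_identical(hb$indices,
                   oracle_hole_boundary(pos, root, tip, 0.0046, 20))
  d_root <- sqrt(rowSums(pos^2))
  expect_true(all(diff(d_root[hb$indices]) > 0))
  seg <- sqrt(rowSums((hb$points[-1, , drop = FALSE] -
                         hb$points[-nrow(hb$points), , drop = FALSE])^2))
  expect_true(all(seg <= 0.0046))
  # single point terminates immediately
  one <- find_hole_boundary(rbind(c(0.02, 0.01, 0)), root, tip, cfg)
  expect_equal(one$indices, 1L)
  # radius below the minimum pairwise distance: only the start point
  tiny <- completion_config(search_radius = 1e-4, fill_spacing = 0.003)
  hb2 <- find_hole_boundary(pos, root, tip, tiny)
  expect_length(hb2$indices, 1)
  # randomized half-clouds against the oracle
  for (seed in 1:5) {
    set.seed(seed)
    rp <- cbind(runif(150, 0.01, 0.09), runif(150, 1e-4, 0.04),
                runif(150, 0, 0.02))
    hbr <- find_hole_boundary(rp, root, tip, cfg)
    expect_identical(hbr$indices,
                     oracle_hole_boundary(rp, root, tip, 0.0046, 20))
  }
})

test_that("completing a touching symmetric leaf adds almost nothing", {
  # tapered lamina whose base sits one spacing from the root: the tip lies
  # on the midrib, the leaf is balanced, and there is no hole to fill
  sc <- generate_rosette(rosette_spec(n_leaves = 1, seed = 4,
                                      leaf_length_sd = 0, inner_gap = 0.003,
                                      inclination = 0, droop = 0,
                                      inclination_jitter = 0,
                                      root_occlusion_range = c(0, 0)))
  pos <- sc$full$positions[sc$labels_full == 1, ]
  root <- structure(c(0, 0, 0), class = "root_point")
  lf <- leaf_cloud(point_cloud(pos, frame = "world"), root)
  cl <- complete_leaf(lf, root, completion_config(fill_spacing = 0.003))
  expect_lt(sum(cl$synthetic) / n_points(lf$points), 0.05)
  # completion is purely additive: originals first, unchanged
  expect_equal(cl$points$positions[seq_len(n_points(lf$points)), ], pos)
})

test_that("mirror completion restores a half leaf to balance", {
  sc <- generate_rosette(rosette_spec(n_leaves = 1, seed = 5,
                                      leaf_length_sd = 0,
                                      root_occlusion_range = c(0, 0)))
  pos <- sc$full$positions[sc$labels_full == 1, ]
  root <- structure(c(0, 0, 0), class = "root_point")
  tip0 <- pos[which.max(rowSums(pos^2)), ]
  side <- rosettecomplete:::axis_side(pos, root, tip0)
  half <- pos[side <= 0, , drop = FALSE]  # delete one side entirely
  lf <- leaf_cloud(point_cloud(half, frame = "world"), root)
  cfg <- rosettecomplete:::resolve_completion_config(
    completion_config(), lf$points)
  cl <- complete_leaf(lf, root, cfg)
  ds <- radius_downsample(cl$points, cfg$final_downsample_radius)
  out <- leaf_cloud(ds, root)
  out$tip <- lf$tip
  expect_lte(symmetry_ratio(out, root)$delta, 0.23)
  # superset property survives the whole chain
  expect_equal(cl$points$positions[seq_len(nrow(half)), ], half)
})

test_that("root-side occlusion is repaired to near-truth leaf area", {
  sc <- generate_rosette(rosette_spec(n_leaves = 1, seed = 8,
                                      leaf_length_sd = 0,
                                      root_occlusion_range = c(0.3, 0.3)))
  vis <- sc$visible$positions[sc$labels_visible == 1, ]
  truth <- sc$truth$leaf_areas[1]
  root <- structure(c(0, 0, 0), class = "root_point")
  lf <- leaf_cloud(point_cloud(vis, frame = "world"), root)
  cfg <- rosettecomplete:::resolve_completion_config(
    completion_config(), lf$points)
  raw_area <- mesh_area(triangulate(lf$points))
  expect_gte(100 * (1 - raw_area / truth), 25)  # uncompleted deficit
  cl <- complete_leaf(lf, root, cfg)
  ds <- radius_downsample(cl$points, cfg$final_downsample_radius)
  comp_area <- mesh_area(triangulate(ds))
  expect_lte(abs(comp_area / truth - 1), 0.15)
})

test_that("whole-plant completion is additive, covered and deterministic", {
  sc <- generate_rosette(rosette_spec(n_leaves = 6, leaf_length_mean = 0.06,
                                      leaf_length_sd = 0.005, seed = 31,
                                      asymmetry = 0.5))
  seg <- classify_plant_soil(
    region_grow_color(sc$visible, 0.005, 40, 50), sc$visible)
  c1 <- complete_plant(seg$plant, seg$soil)
  c2 <- complete_plant(seg$plant, seg$soil)
  expect_identical(c1$positions, c2$positions)  # no randomness anywhere
  expect_identical(attr(c1, "synthetic"), attr(c2, "synthetic"))
  # coverage: every input point lies within the downsample radius of a
  # retained point (brute-force nearest-neighbor audit)
  r <- attr(c1, "config")$final_downsample_radius
  outp <- c1$positions
  min_d <- vapply(seq_len(n_points(seg$plant)), function(i) {
    p <- seg$plant$positions[i, ]
    sqrt(min((outp[, 1] - p[1])^2 + (outp[, 2] - p[2])^2 +
               (outp[, 3] - p[3])^2))
  }, numeric(1))
  expect_true(all(min_d <= r + 1e-12))
  # original points never move: retained originals are exact input rows
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  orig_out <- c1$positions[!attr(c1, "synthetic"), , drop = FALSE]
  expect_true(all(key(orig_out) %in% key(seg$plant$positions)))
})

test_that("a plant with no leaf clusters is only downsampled", {
  tp <- toy_plant(2)
  cfg <- completion_config(leaf_min_cluster_size = 1e6,
                           fill_spacing = 0.004)
  out <- complete_plant(tp$plant, tp$soil, cfg)
  expect_identical(out$positions,
                   radius_downsample(tp$plant, 0.5 * 0.004)$positions)
  expect_false(any(attr(out, "synthetic")))
})

test_that("completed clouds export with their synthetic-flag sidecar", {
  sc <- generate_rosette(rosette_spec(n_leaves = 4, leaf_length_mean = 0.05,
                                      leaf_length_sd = 0.003, seed = 19))
  seg <- classify_plant_soil(
    region_grow_color(sc$visible, 0.005, 40, 50), sc$visible)
  comp <- complete_plant(seg$plant, seg$soil)
  stem <- file.path(withr::local_tempdir(), "plant")
  export_completed_cloud(comp, stem)
  back <- read_point_cloud(paste0(stem, ".ply"), frame = "world")
  expect_equal(back$positions, comp$positions, tolerance = 1e-6)
  flags <- read.csv(paste0(stem, "_synthetic.csv"))
  expect_equal(nrow(flags), n_points(comp))
  expect_identical(flags$synthetic == 1, unname(attr(comp, "synthetic")))
})
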