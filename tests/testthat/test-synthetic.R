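test_that("scenes carry one label per leaf plus soil, deterministically", {
  spec <- rosette_spec(n_leaves = 6, leaf_length_mean = 0.06,
                       leaf_length_sd = 0.004, seed = 2)
  sc <- generate_rosette(spec)
  expect_setequal(unique(sc$labels_full), 0:6)
  expect_equal(length(sc$labels_full), n_points(sc$full))
  sc2 <- generate_rosette(spec)
  expect_identical(sc$full$positions, sc2$full$positions)
  expect_identical(sc$full$colors, sc2$full$colors)
  expect_identical(sc$visible$positions, sc2$visible$positions)
  # truth total equals the per-leaf sum
  expect_equal(sc$truth$total_area, sum(sc$truth$leaf_areas))
  # visible is a subset of full
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(sc$visible$positions) %in% key(sc$full$positions)))
})

test_that("scene generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_rosette(rosette_spec(n_leaves = 3, seed = 77)))
  expect_identical(runif(1), before)
})

test_that("flat-leaf truth matches the closed-form lamina area", {
  L <- 0.1
  wr <- 0.28
  sc <- generate_rosette(rosette_spec(n_leaves = 1, leaf_length_mean = L,
                                      leaf_length_sd = 0, width_ratio = wr,
                                      inclination = 0, droop = 0,
                                      inclination_jitter = 0, seed = 3))
  # elliptic half-width profile integrates to (pi / 2) wr L^2
  expect_lt(abs(sc$truth$leaf_areas[1] / (pi / 2 * wr * L^2) - 1), 0.01)
})

test_that("z-buffer visibility keeps exactly the per-cell top layer", {
  # single horizontal plane: everything visible
  plane <- grid_cloud(8, 0.004)
  expect_identical(simulate_top_view(plane, 0.003, 0.002)$positions,
                   plane$positions)
  # two stacked squares far apart in z: overlapped lower region removed
  top <- grid_cloud(8, 0.004)$positions
  top[, 3] <- 0.1
  both <- point_cloud(rbind(grid_cloud(8, 0.004)$positions, top),
                      frame = "world")
  vis <- simulate_top_view(both, 0.003, 0.002)
  expect_identical(vis$positions, top)
  # subset property + per-cell max-z oracle on a random cloud
  cl <- random_cloud(400, seed = 17)
  v <- simulate_top_view(cl, 0.01, 0.003)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(v$positions) %in% key(cl$positions)))
  cell <- 0.01
  ix <- floor((cl$positions[, 1] - cl$positions[1, 1]) / cell)
  iy <- floor((cl$positions[, 2] - cl$positions[1, 2]) / cell)
  zmax <- tapply(cl$positions[, 3], paste(ix, iy), max)
  keep <- cl$positions[, 3] >= zmax[paste(ix, iy)] - 0.003
  expect_identical(v$positions, cl$positions[keep, , drop = FALSE])
})

test_that("the standard benchmark draws documented, deterministic scenes", {
  scenes <- standard_benchmark(6, base_seed = 42)
  expect_length(scenes, 6)
  asym <- vapply(scenes, function(s) s$spec$asymmetry, numeric(1))
  expect_identical(asym, rep(c(0.6, 0), 3))
  n <- vapply(scenes, function(s) s$spec$n_leaves, integer(1))
  expect_true(all(n >= 8 & n <= 14))
  len <- vapply(scenes, function(s) s$spec$leaf_length_mean, numeric(1))
  expect_true(all(len >= 0.06 & len <= 0.15))
  incl <- vapply(scenes, function(s) s$spec$inclination, numeric(1))
  expect_true(all(incl >= 15 * pi / 180 & incl <= 45 * pi / 180))
  again <- standard_benchmark(6, base_seed = 42)
  for (i in seq_along(scenes))
    expect_identical(scenes[[i]]$full$positions, again[[i]]$full$positions)
  # occlusion is active in every scene
  shrink <- vapply(scenes, function(s)
    1 - n_points(s$visible) / n_points(s$full), numeric(1))
  expect_true(all(shrink >= 0.10))
  # occlusion removes points preferentially near the root
  for (s in scenes[1:2]) {
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    vis <- key(s$full$positions) %in% key(s$visible$positions)
    leafy <- s$labels_full > 0
    r <- sqrt(rowSums(s$full$positions[, 1:2]^2))
    expect_lt(median(r[leafy & !vis]), median(r[leafy & vis]))
  }
})

test_that("scene export writes cloud pairs with a truth sidecar", {
  skip_if_not_installed("jsonlite")
  sc <- generate_rosette(rosette_spec(n_leaves = 3, leaf_length_mean = 0.05,
                                      leaf_length_sd = 0.003, seed = 9))
  dir <- withr::local_tempdir()
  paths <- export_scene(sc, dir, "s1")
  expect_true(all(file.exists(file.path(dir, c("s1_full.ply",
                                               "s1_visible.ply",
                                               "s1_truth.json")))))
  back <- read_point_cloud(file.path(dir, "s1_full.ply"), frame = "world")
  expect_equal(back$positions, sc$full$positions, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "s1_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$total_area, sc$truth$total_area, tolerance = 1e-9)
})
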