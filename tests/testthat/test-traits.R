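test_that("heights follow the top/soil/pot-edge arithmetic", {
  plant <- point_cloud(rbind(c(0, 0, 0.30), c(0.1, 0, 0.1)), frame = "world")
  soil <- point_cloud(rbind(c(0.2, 0, 0), c(0.3, 0, 0)), frame = "world")
  h <- estimate_heights(plant, soil, traits_config(pot_edge_z = 0.02))
  expect_equal(h$H_abs, 0.30)
  expect_equal(h$H_rel, 0.28)
  # adding a lower point changes nothing
  plant2 <- point_cloud(rbind(plant$positions, c(0, 0.1, 0.05)),
                        frame = "world")
  expect_equal(estimate_heights(plant2, soil,
                                traits_config(pot_edge_z = 0.02)), h)
  # xy rigid motion invariance
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- function(cl) point_cloud(cl$positions %*% t(R) +
                                    rep(c(0.5, -0.3, 0), each = n_points(cl)),
                                  frame = "world")
  expect_equal(estimate_heights(rot(plant), rot(soil),
                                traits_config(pot_edge_z = 0.02)), h)
})

test_that("projected area counts occupied grid cells", {
  one <- point_cloud(rbind(c(0.5, 0.5, 9)), frame = "world")
  expect_equal(projected_area(one, 0.01), 1e-4)
  # dense unit square within 2% of 1 m^2
  g <- seq(0, 1 - 0.0025, by = 0.0025)  # sample [0, 1) at cell/4
  sq <- point_cloud(as.matrix(expand.grid(x = g, y = g, z = 0)),
                    frame = "world")
  expect_lt(abs(projected_area(sq, 0.01) - 1), 0.02)
  # invariant to point permutation and z-translation
  cl <- random_cloud(300, seed = 2)
  a0 <- projected_area(cl, 0.004)
  perm <- rosettecomplete:::subset_cloud(cl, sample(n_points(cl)))
  expect_equal(projected_area(perm, 0.004), a0)
  up <- point_cloud(cl$positions + rep(c(0, 0, 5), each = n_points(cl)),
                    frame = "world")
  expect_equal(projected_area(up, 0.004), a0)
  # monotone non-decreasing under adding points
  more <- rosettecomplete:::bind_clouds(cl, random_cloud(100, seed = 4))
  expect_gte(projected_area(more, 0.004), a0)
})

test_that("triangulation handles the textbook small cases", {
  tri <- triangulate(point_cloud(rbind(c(0, 0, 0), c(0.01, 0, 0),
                                       c(0, 0.01, 0)), frame = "world"),
                     max_edge = 0.05)
  expect_equal(nrow(tri$triangles), 1)
  expect_equal(mesh_area(tri), 0.5 * 0.01 * 0.01, tolerance = 1e-12)
  # unit square: two triangles, area exactly 1 (corner ON the ball allowed)
  sq <- triangulate(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                      c(0, 1, 0)), frame = "world"),
                    max_edge = 2)
  expect_equal(nrow(sq$triangles), 2)
  expect_equal(mesh_area(sq), 1, tolerance = 1e-9)
  expect_true(oracle_check_mesh(sq, 2))
  # collinear points yield an empty mesh, which is valid
  lin <- triangulate(point_cloud(cbind(seq(0, 0.02, by = 0.005), 0, 0),
                                 frame = "world"), max_edge = 0.02)
  expect_equal(nrow(lin$triangles), 0)
  expect_equal(mesh_area(lin), 0)
  expect_error(triangulate(point_cloud(rbind(c(0, 0, 0)), frame = "world")),
               "at least 3")
})

test_that("planar grids triangulate to their exact area", {
  s <- 0.003
  for (n in 4:6) {
    m <- triangulate(grid_cloud(n, s), max_edge = 1.5 * s)
    expect_equal(mesh_area(m), (n - 1)^2 * s^2, tolerance = 1e-9)
    expect_true(oracle_check_mesh(m, 1.5 * s))
  }
  # refinement: exactness holds as the grid grows
  for (n in c(8, 10)) {
    m <- triangulate(grid_cloud(n, s), max_edge = 1.5 * s)
    expect_equal(mesh_area(m), (n - 1)^2 * s^2, tolerance = 1e-9)
  }
})

test_that("a sampled disc reproduces pi r^2 within 3 percent", {
  g <- seq(-0.1, 0.1, by = 0.002)
  xy <- as.matrix(expand.grid(x = g, y = g))
  xy <- xy[rowSums(xy^2) <= 0.01, ]
  m <- triangulate(point_cloud(cbind(xy, 0), frame = "world"),
                   max_edge = 0.003)
  expect_lt(abs(mesh_area(m) / (pi * 0.01) - 1), 0.03)
})

test_that("mesh area is additive over disjoint meshes", {
  m1 <- triangulate(grid_cloud(4, 0.01), max_edge = 0.015)
  shifted <- point_cloud(grid_cloud(4, 0.01)$positions +
                           rep(c(1, 0, 0), each = 16), frame = "world")
  m2 <- triangulate(shifted, max_edge = 0.015)
  both <- triangulate(rosettecomplete:::bind_clouds(
    grid_cloud(4, 0.01), shifted), max_edge = 0.015)
  expect_equal(mesh_area(both), mesh_area(m1) + mesh_area(m2),
               tolerance = 1e-9)
})

test_that("mesh export writes readable PLY and OBJ", {
  m <- triangulate(grid_cloud(4, 0.01), max_edge = 0.015)
  ply <- withr::local_tempfile(fileext = ".ply")
  obj <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, ply, "ply")
  write_mesh(m, obj, "obj")
  expect_true(any(grepl("element face 18", readLines(ply))))
  expect_equal(sum(grepl("^f ", readLines(obj))), nrow(m$triangles))
})

test_that("allometric fits recover linear relations", {
  a <- c(0.01, 0.02, 0.03, 0.04)
  fit <- fit_allometry(a, 2 * a + 1, "weight_g")
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # constant responses: degenerate convention R^2 = 1
  fitc <- fit_allometry(a, rep(5, 4), "volume_mL")
  expect_equal(fitc$slope, 0, tolerance = 1e-12)
  expect_true(fitc$degenerate)
  expect_equal(fitc$r_squared, 1)
  # noisy recovery at the stated noise level
  set.seed(99)
  # predictor spread wide enough that the +/-0.1 slope band is ~3 sigma
  x <- runif(100, 0, 0.1)
  y <- 3 * x + rnorm(100, 0, 0.01)
  fitn <- fit_allometry(x, y, "weight_g")
  expect_gte(fitn$slope, 2.9)
  expect_lte(fitn$slope, 3.1)
  # predictions clamp at zero
  expect_equal(predict_allometry(fit_allometry(a, 2 * a - 1, "weight_g"),
                                 0), 0)
  expect_error(fit_allometry(0.01, 5, "weight_g"), "at least 2")
  expect_error(fit_allometry(c(0.01, 0.01), c(1, 2), "weight_g"),
               "not all be equal")
})

test_that("per-leaf area summation uses the labels completion carries", {
  sc <- generate_rosette(rosette_spec(n_leaves = 5, leaf_length_mean = 0.06,
                                      leaf_length_sd = 0.004, seed = 13))
  plant_idx <- which(sc$labels_full > 0)
  plant <- rosettecomplete:::subset_cloud(sc$full, plant_idx)
  tot <- total_leaf_area(plant, labels = sc$labels_full[plant_idx])
  expect_lt(abs(tot / sc$truth$total_area - 1), 0.05)
  expect_error(total_leaf_area(plant, labels = 1:3), "one label per point")
})
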