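# Brute-force oracles, independent of the package's spatial kernels.
# Everything here is O(n^2) or worse on purpose: slow, simple, checkable.

# random colored cloud in a box of the given extent
random_cloud <- function(n, seed, extent = 0.1, n_hues = 4) {
  set.seed(seed)
  pos <- cbind(runif(n, 0, extent), runif(n, 0, extent), runif(n, 0, extent))
  hues <- matrix(sample(0:255, 3 * n_hues, replace = TRUE), ncol = 3)
  cols <- hues[sample(n_hues, n, replace = TRUE), , drop = FALSE]
  point_cloud(pos, colors = cols, frame = "world")
}

dist_matrix <- function(pos) as.matrix(stats::dist(pos))

# connected components of an adjacency matrix, as a partition (list of
# sorted index vectors ordered by smallest member)
oracle_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  out <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- unname(which(apply(adj[frontier, , drop = FALSE], 2, any) &
                            !seen))
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    out[[length(out) + 1]] <- as.integer(sort(comp))
  }
  out[order(vapply(out, min, integer(1)))]
}

# explicit neighbor-color graph of region growing
oracle_region_grow <- function(cloud, radius, color_thr) {
  d <- dist_matrix(cloud$positions)
  cd2 <- dist_matrix(cloud$colors)^2
  adj <- d <= radius & cd2 <= color_thr^2
  diag(adj) <- TRUE
  oracle_components(adj)
}

# statistical outlier removal: indices kept
oracle_sor_keep <- function(cloud, k, mult) {
  d <- dist_matrix(cloud$positions)
  diag(d) <- Inf
  md <- apply(d, 1, function(r) mean(sort(r)[seq_len(k)]))
  which(md <= mean(md) + mult * stats::sd(md))
}

# raw closest-edge membership
oracle_edge_raw <- function(pos, root, var_mul, sigma_mode = "std") {
  dd <- sqrt(colSums((t(pos) - root[1:3])^2))
  sigma <- if (length(dd) < 2) 0 else if (sigma_mode == "std") stats::sd(dd)
    else sum(dd) / (length(dd) - 1)
  which(dd <= min(dd) + var_mul * sigma + 1e-9)
}

# left/right counts about the root->tip xy axis
oracle_symmetry <- function(pos, root, tip) {
  cr <- (tip[1] - root[1]) * (pos[, 2] - root[2]) -
    (tip[2] - root[2]) * (pos[, 1] - root[1])
  nl <- sum(cr > 0)
  nr <- sum(cr < 0)
  list(n_left = nl, n_right = nr,
       delta = if (nl + nr == 0) 0 else 2 * abs(nl - nr) / (nl + nr))
}

# literal replay of the hole-boundary march with exhaustive neighbor search
oracle_hole_boundary <- function(pos, root, tip, r, n_s) {
  d_root <- sqrt(colSums((t(pos) - root[1:3])^2))
  nrm <- sqrt((tip[1] - root[1])^2 + (tip[2] - root[2])^2)
  d_axis <- abs((tip[1] - root[1]) * (pos[, 2] - root[2]) -
                  (tip[2] - root[2]) * (pos[, 1] - root[1])) / nrm
  near <- order(d_root)[seq_len(min(n_s, nrow(pos)))]
  cur <- near[which.min(d_axis[near])]
  boundary <- cur
  repeat {
    dd <- sqrt(colSums((t(pos) - pos[cur, ])^2))
    cand <- which(dd <= r & d_root > d_root[cur])
    if (length(cand) == 0) break
    cur <- cand[which.min(d_axis[cand])]
    boundary <- c(boundary, cur)
  }
  boundary
}

# every triangle of a mesh must satisfy the acceptance conditions:
# (a) no other point strictly inside its minimum enclosing ball,
# (b) all edges <= max_edge; checked by exhaustive enumeration
oracle_check_mesh <- function(mesh, max_edge, tol = 1e-9) {
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$triangles))) {
    tr <- mesh$triangles[i, ]
    A <- v[tr[1], ]; B <- v[tr[2], ]; C <- v[tr[3], ]
    e <- c(sqrt(sum((A - B)^2)), sqrt(sum((A - C)^2)), sqrt(sum((B - C)^2)))
    if (any(e > max_edge + tol)) return(FALSE)
    ab2 <- sum((B - A)^2); ac2 <- sum((C - A)^2); bc2 <- sum((C - B)^2)
    ee <- c(ab2, ac2, bc2)
    longest <- which.max(ee)
    if (ee[longest] >= sum(ee[-longest])) {
      pq <- switch(longest, rbind(A, B), rbind(A, C), rbind(B, C))
      cen <- colMeans(pq)
      rad <- sqrt(ee[longest]) / 2
    } else {
      a <- B - A; b <- C - A
      aa <- sum(a^2); bb <- sum(b^2); ab <- sum(a * b)
      det <- aa * bb - ab^2
      s <- 0.5 * bb * (aa - ab) / det
      t <- 0.5 * aa * (bb - ab) / det
      cen <- A + s * a + t * b
      rad <- sqrt(sum((cen - A)^2))
    }
    dd <- sqrt(colSums((t(v) - cen)^2))
    dd[tr] <- Inf
    if (any(dd < rad - tol)) return(FALSE)
  }
  TRUE
}

# planar grid cloud (n x n, spacing s, z = 0)
grid_cloud <- function(n, s = 0.003) {
  g <- seq(0, by = s, length.out = n)
  point_cloud(as.matrix(expand.grid(x = g, y = g, z = 0)), frame = "world")
}

# one small pre-segmented plant: leaves as separated flat color-coded
# blobs around a root at the origin, soil disc below
toy_plant <- function(n_leaves = 4, seed = 1) {
  set.seed(seed)
  s <- 0.004
  pos <- list(); cols <- list()
  for (i in seq_len(n_leaves)) {
    az <- 2 * pi * (i - 1) / n_leaves
    g <- expand.grid(u = seq(0.03, 0.08, by = s), v = seq(-0.01, 0.01, by = s))
    p <- cbind(g$u * cos(az) - g$v * sin(az), g$u * sin(az) + g$v * cos(az),
               0.01 + 0.2 * g$u)
    pos[[i]] <- p
    cols[[i]] <- matrix(rep(c(40 + 60 * ((i - 1) %% 3), 170,
                              60 + 30 * (i %% 2)), each = nrow(p)), ncol = 3)
  }
  plant <- point_cloud(do.call(rbind, pos), colors = do.call(rbind, cols),
                       frame = "world")
  gs <- seq(-0.1, 0.1, by = 0.005)
  sxy <- as.matrix(expand.grid(gs, gs))
  sxy <- sxy[rowSums(sxy^2) <= 0.01, ]
  soil <- point_cloud(cbind(sxy, 0),
                      colors = matrix(rep(c(135L, 90L, 65L), each = nrow(sxy)),
                                      ncol = 3),
                      frame = "world")
  list(plant = plant, soil = soil)
}
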