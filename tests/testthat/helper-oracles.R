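# Independent oracles and small fixtures used across test files.

# Point-to-triangle distance by an independent formulation: distance to the
# supporting plane when the orthogonal projection falls inside the triangle
# (barycentric test), otherwise the minimum point-to-edge-segment distance.
# Vectorized over triangles for one query point.
oracle_point_tri_dist <- function(p, A, B, C) {
  n <- cbind((B - A)[, 2] * (C - A)[, 3] - (B - A)[, 3] * (C - A)[, 2],
             (B - A)[, 3] * (C - A)[, 1] - (B - A)[, 1] * (C - A)[, 3],
             (B - A)[, 1] * (C - A)[, 2] - (B - A)[, 2] * (C - A)[, 1])
  nn <- rowSums(n^2)
  ap <- sweep(-A, 2, p, "+")
  t_ <- rowSums(ap * n) / nn
  proj <- sweep(n * t_, 2, p, "-") * -1       # p - t*n
  # barycentric coordinates of proj
  v0 <- C - A; v1 <- B - A; v2 <- proj - A
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01 * d01
  u <- (d11 * d20 - d01 * d21) / den
  v <- (d00 * d21 - d01 * d20) / den
  inside <- u >= 0 & v >= 0 & (u + v) <= 1
  plane_d <- abs(t_) * sqrt(nn)
  seg_d <- function(P, Q) {
    pq <- Q - P
    tt <- rowSums(sweep(-P, 2, p, "+") * pq) / rowSums(pq^2)
    tt <- pmin(pmax(tt, 0), 1)
    cl <- P + pq * tt
    sqrt(rowSums(sweep(cl, 2, p)^2))
  }
  edge_d <- pmin(seg_d(A, B), seg_d(B, C), seg_d(C, A))
  ifelse(inside, plane_d, edge_d)
}

# Brute-force unsigned point-to-mesh distance: min over all triangles.
oracle_point_mesh_dist <- function(p, mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  min(oracle_point_tri_dist(p, v[tr[, 1], , drop = FALSE],
                            v[tr[, 2], , drop = FALSE],
                            v[tr[, 3], , drop = FALSE]))
}

# Unit cube mesh [0,1]^3 with outward orientation (12 triangles).
cube_mesh <- function(scale = 1) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * scale
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),     # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),     # z = 1 face (+z)
    c(1, 2, 5), c(2, 6, 5),     # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),     # y = 1 (+y)
    c(1, 5, 3), c(3, 5, 7),     # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))     # x = 1 (+x)
  surface_mesh(v, f)
}

# Analytic two-channel stack: balls of constant intensity (no rendering),
# for fast reconstruction tests. `balls` is a list of list(center, radius).
analytic_ball_stack <- function(balls, spacing = c(4, 4, 3),
                                dims = c(64, 64, 85),
                                origin = NULL, intensity = 180) {
  origin <- origin %||% (-(dims - 1) / 2 * spacing)
  co <- lapply(1:3, function(i) origin[i] + (seq_len(dims[i]) - 1) * spacing[i])
  a <- array(0, dims)
  for (b in balls) {
    r2 <- outer(outer((co[[1]] - b$center[1])^2, (co[[2]] - b$center[2])^2,
                      "+"), (co[[3]] - b$center[3])^2, "+")
    a <- a + intensity * (r2 <= b$radius^2)
  }
  voxel_stack(a, array(0, dims), spacing, origin)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Toy distance table of the worked invasion example: two reference organoids
# with normalized distances [0,10,20,30] and [0,4,8,12].
toy_invasion_table <- function() {
  data.frame(
    organoid_id = rep(c("A", "B"), each = 4),
    group = "reference",
    cell_id = paste0("c", 1:8),
    x = 0, y = 0, z = 0,
    distance_um = c(0, 10, 20, 30, 0, 4, 8, 12),
    stringsAsFactors = FALSE)
}
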