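# Padding, surface reconstruction, spot detection and measured depths.

test_that("blank-slice padding appends zero slices at the bottom", {
  sc <- generate_scene(60, n_nuclei = 300, n_tumor = 0, seed = 4)
  st <- render_stack(sc, imaging_params(n_slices = 85, z_step = 3,
                                        xy_pixel = 6))
  p <- pad_stack(st, 50)
  expect_equal(dim(p$nuclear)[3], 135)
  expect_true(all(p$nuclear[, , 1:50] == 0))
  # original voxels keep their physical positions
  expect_equal(p$origin[3], st$origin[3] - 50 * 3)
  expect_equal(p$nuclear[, , 51], st$nuclear[, , 1])

  expect_identical(pad_stack(st, 0), st)

  z <- voxel_stack(array(0, c(4, 4, 10)), array(0, c(4, 4, 10)),
                   c(1, 1, 1))
  z5 <- pad_stack(z, 5)
  expect_equal(dim(z5$nuclear)[3], 15)
  expect_true(all(z5$nuclear == 0))
})

test_that("otsu threshold separates a bimodal histogram", {
  set.seed(12)
  x <- c(rnorm(500, 10, 2), rnorm(500, 100, 5))
  t <- otsu_threshold(x)
  # the threshold lands between the modes and classifies almost perfectly
  expect_gt(t, 14); expect_lt(t, 86)
  expect_gte(mean((x > t) == rep(c(FALSE, TRUE), each = 500)), 0.995)
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("a noise-free sphere reconstructs at its analytic radius", {
  st <- analytic_ball_stack(list(list(center = c(0, 0, 0), radius = 100)),
                            dims = c(64, 64, 85))
  m1 <- reconstruct_surface(st)
  expect_equal(m1$provenance$pass, 1L)
  rad <- sqrt(rowSums(m1$vertices^2))
  tol <- max(sqrt(sum(st$spacing^2)), 25 / 2)
  expect_true(all(abs(rad - 100) < tol))
  expect_lt(abs(mean(rad) - 100), 3)
})

test_that("uniform stacks give an empty-surface error", {
  u <- voxel_stack(array(7, c(8, 8, 8)), array(0, c(8, 8, 8)), c(1, 1, 1))
  expect_error(reconstruct_surface(u), "empty surface|uniform")
})

test_that("only the largest of two disjoint components is surfaced", {
  st <- analytic_ball_stack(list(list(center = c(-30, -30, -20), radius = 90),
                                 list(center = c(100, 100, 80), radius = 25)),
                            spacing = c(4, 4, 3), dims = c(72, 72, 85))
  m1 <- reconstruct_surface(st)
  m2 <- outside_mask_resurface(st, m1)
  # volume matches the big sphere, not the union
  expect_lt(abs(mesh_volume(m2) / (4 / 3 * pi * 90^3) - 1), 0.05)
  # every vertex is near the big sphere's shell
  rad <- sqrt(rowSums(sweep(m2$vertices, 2, c(-30, -30, -20))^2))
  expect_true(all(abs(rad - 90) < 15))
})

test_that("pass-2 resurfacing preserves volume for an interior sphere", {
  st <- analytic_ball_stack(list(list(center = c(0, 0, 0), radius = 90)),
                            dims = c(60, 60, 80))
  m1 <- reconstruct_surface(st)
  m2 <- outside_mask_resurface(st, m1)
  expect_true(is_watertight(m2))
  expect_equal(m2$provenance$pass, 2L)
  expect_lt(abs(mesh_volume(m2) / mesh_volume(m1) - 1), 0.05)
  expect_error(outside_mask_resurface(st, surface_mesh(matrix(0, 0, 3),
                                                       matrix(0L, 0, 3))),
               "empty")
})

test_that("pass-2 vertex positions are invariant to the fill value", {
  st <- analytic_ball_stack(list(list(center = c(0, 0, 0), radius = 80)),
                            dims = c(52, 52, 70))
  m1 <- reconstruct_surface(st)
  m150 <- outside_mask_resurface(st, m1, fill_value = 150)
  m255 <- outside_mask_resurface(st, m1, fill_value = 255)
  expect_equal(m150$vertices, m255$vertices, tolerance = 1e-9)
})

test_that("a surface truncated by the stack top tracks the organoid, not the boundary", {
  # sphere center high enough that its top is cut off by the last slice
  dims <- c(64, 64, 60); spacing <- c(4, 4, 3)
  origin <- -(dims - 1) / 2 * spacing
  top_z <- origin[3] + (dims[3] - 1) * spacing[3]     # 88.5
  st <- analytic_ball_stack(list(list(center = c(0, 0, 30), radius = 80)),
                            spacing = spacing, dims = dims)
  m1 <- reconstruct_surface(st)
  m2 <- outside_mask_resurface(st, m1)
  expect_true(is_watertight(m2))
  # pass 1 caps flat right at/above the top plane; pass 2 continues upward
  expect_lt(max(m1$vertices[, 3]), top_z + 2 * spacing[3])
  expect_gt(max(m2$vertices[, 3]), top_z + 2 * spacing[3])
  # near the top plane, pass-1 cap spans the full cross-section (center
  # included) while pass-2 vertices sit near the shell
  cross_r <- sqrt(80^2 - (top_z - 30)^2)              # analytic section radius
  near1 <- abs(m1$vertices[, 3] - top_z) < spacing[3]
  near2 <- abs(m2$vertices[, 3] - top_z) < spacing[3]
  rr1 <- sqrt(rowSums(m1$vertices[near1, 1:2, drop = FALSE]^2))
  rr2 <- sqrt(rowSums(m2$vertices[near2, 1:2, drop = FALSE]^2))
  expect_lt(min(rr1), 0.3 * cross_r)                  # flat cap reaches axis
  expect_gt(min(rr2), 0.7 * cross_r)                  # pass 2 hugs the wall
})

test_that("well-separated rendered cells are each detected once", {
  set.seed(2)
  # 20 cells on a wide lattice, far more than 10 um apart
  grid <- as.matrix(expand.grid(x = c(-80, -40, 0, 40, 80),
                                y = c(-60, -20, 20, 60), z = 0))
  sc <- generate_scene(100, n_nuclei = 0, n_tumor = 20,
                       depth_law = depth_law("fixed", values = rep(0, 20)),
                       seed = 1)
  sc$tumor_positions <- grid
  st <- render_stack(sc, imaging_params(n_slices = 40, z_step = 3,
                                        xy_pixel = 4))
  sp <- detect_spots(st)
  expect_equal(nrow(sp$positions), 20)
  nn <- apply(sp$positions, 1, function(p)
    min(sqrt(colSums((t(grid) - p)^2))))
  expect_true(all(nn < max(st$spacing)))
})

test_that("a blank tumor channel yields zero spots", {
  sc <- generate_scene(25, n_nuclei = 10, n_tumor = 0, seed = 1)
  st <- render_stack(sc, imaging_params(n_slices = 20, z_step = 3,
                                        xy_pixel = 6))
  expect_equal(nrow(detect_spots(st)$positions), 0)
})

test_that("sub-diameter cell pairs resolve deterministically", {
  sc <- generate_scene(50, n_nuclei = 0, n_tumor = 2,
                       depth_law = depth_law("fixed", values = c(0, 0)),
                       seed = 1)
  sc$tumor_positions <- rbind(c(-2, 0, 0), c(2, 0, 0))    # 4 um apart
  st <- render_stack(sc, imaging_params(n_slices = 30, z_step = 3,
                                        xy_pixel = 4))
  n1 <- nrow(detect_spots(st)$positions)
  n2 <- nrow(detect_spots(st)$positions)
  expect_true(n1 %in% c(1L, 2L))
  expect_identical(n1, n2)
})

test_that("measured depths recover planted truth on a noise-free sphere", {
  sc <- generate_scene(100, n_tumor = 40,
                       depth_law = depth_law("exponential", scale = 20),
                       seed = 6)
  st <- pad_stack(render_stack(sc, imaging_params(xy_pixel = 4)), 50)
  m2 <- outside_mask_resurface(st, reconstruct_surface(st))
  dt <- shortest_distance(detect_spots(st), m2)
  truth <- scene_to_truth_table(sc)
  nn <- apply(as.matrix(dt[, c("x", "y", "z")]), 1, function(p)
    which.min(colSums((t(as.matrix(truth[, c("x", "y", "z")])) - p)^2)))
  err <- dt$distance_um - truth$distance_um[nn]
  tol <- max(sqrt(sum(st$spacing^2)), 12.5)
  expect_lt(sqrt(mean(err^2)), tol)
  # volume and area of the reconstructed surface track the analytic sphere
  expect_lt(abs(mesh_volume(m2) / (4 / 3 * pi * 1e6) - 1), 0.05)
  expect_lt(abs(mesh_area(m2) / (4 * pi * 1e4) - 1), 0.05)
})

test_that("translating the scene by a lattice vector leaves depths stable", {
  mk <- function(center) {
    st <- analytic_ball_stack(list(list(center = center, radius = 80)),
                              spacing = c(4, 4, 3), dims = c(56, 56, 70))
    m2 <- outside_mask_resurface(st, reconstruct_surface(st))
    pts <- sweep(rbind(c(0, 0, 0), c(40, 0, 0), c(0, -90, 0), c(60, 60, 0)),
                 2, center, "+")
    point_mesh_distance(pts, m2)
  }
  d0 <- mk(c(0, 0, 0))
  d1 <- mk(c(4, 4, 3))       # one voxel along each axis
  expect_lt(max(abs(d0 - d1)), sqrt(sum(c(4, 4, 3)^2)))
})
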