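# Open re-implementation of the commercial surface/spot workflow: blank-slice
# padding, two-pass organoid surface reconstruction from the nuclear channel,
# scale-matched tumor spot detection, and exact signed spot-to-surface
# distances.

#' Append blank slices to the bottom of a stack
#'
#' The organoid typically begins at (or close to) the first optical section,
#' so the reconstructed surface would otherwise be truncated at the stack
#' bottom; 50 blank slices are appended below it by default. The coordinate
#' origin shifts so original voxels keep their physical positions.
#'
#' @param stack a `voxel_stack`.
#' @param n_blank number of zero-intensity slices to add (default 50).
#' @return a `voxel_stack` with `n_blank` extra bottom slices.
#' @export
pad_stack <- function(stack, n_blank = 50) {
  if (!is_count(n_blank)) stopf("n_blank must be a non-negative count")
  if (n_blank == 0) return(stack)
  d <- dim(stack$nuclear)
  pad <- array(0, c(d[1], d[2], n_blank))
  new_nuc <- array(0, c(d[1], d[2], d[3] + n_blank))
  new_tum <- new_nuc
  new_nuc[, , seq_len(n_blank)] <- pad
  new_nuc[, , n_blank + seq_len(d[3])] <- stack$nuclear
  new_tum[, , n_blank + seq_len(d[3])] <- stack$tumor
  origin <- stack$origin
  origin[3] <- origin[3] - n_blank * stack$spacing[3]
  out <- voxel_stack(new_nuc, new_tum, stack$spacing, origin)
  attr(out, "n_clipped") <- attr(stack, "n_clipped")
  out
}

# Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
# Replicate-edge padding via index clamping; implemented as a weighted sum
# of axis-shifted copies.
smooth_gauss3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-0.5 * ((-r):r / s)^2)
    w <- w / sum(w)
    n <- d[ax]
    acc <- array(0, d)
    for (k in seq_along(w)) {
      sh <- k - r - 1L
      idx <- pmin(pmax(seq_len(n) + sh, 1L), n)
      acc <- acc + w[k] * switch(ax,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE])
    }
    a <- acc
  }
  a
}

#' Otsu threshold of an intensity array
#'
#' Maximizes between-class variance over a 256-bin histogram.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins histogram bins.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) stopf("constant intensity: no threshold exists")
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
                n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# 6-connected flood fill from seed linear indices within a logical mask;
# returns the reached logical array.
flood_fill <- function(mask, seeds) {
  d <- dim(mask)
  nxy <- d[1] * d[2]
  reached <- array(FALSE, d)
  seeds <- seeds[mask[seeds]]
  reached[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    ai <- arrayInd(frontier, d)
    cand <- c(
      frontier[ai[, 1] > 1] - 1L, frontier[ai[, 1] < d[1]] + 1L,
      frontier[ai[, 2] > 1] - d[1], frontier[ai[, 2] < d[2]] + d[1],
      frontier[ai[, 3] > 1] - nxy, frontier[ai[, 3] < d[3]] + nxy)
    cand <- unique(cand)
    cand <- cand[mask[cand] & !reached[cand]]
    reached[cand] <- TRUE
    frontier <- cand
  }
  reached
}

# Label 6-connected components of a logical 3D mask by frontier expansion;
# returns the logical mask of the largest component.
largest_component <- function(mask) {
  fg <- which(mask)
  if (length(fg) == 0L) return(mask)
  best <- NULL; best_size <- -1L
  remaining <- mask
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- flood_fill(remaining, seed)
    size <- sum(comp)
    if (size > best_size) { best <- comp; best_size <- size }
    remaining <- remaining & !comp
  }
  best
}

# Fill interior cavities: background voxels not 6-connected to the array
# boundary become foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  idx <- array(seq_along(mask), d)
  border <- c(idx[1, , ], idx[d[1], , ], idx[, 1, ], idx[, d[2], ],
              idx[, , 1], idx[, , d[3]])
  outside <- flood_fill(!mask, unique(border))
  !outside
}

# ---------------------------------------------------------------------------
# Marching tetrahedra iso-surface extraction.
#
# Each grid cube is split into the 6 tetrahedra sharing its main diagonal;
# the induced face diagonals match between neighboring cubes, so interpolated
# edge vertices are shared and the resulting mesh is watertight whenever the
# field is below the iso level on the array boundary. Triangles are oriented
# with normals pointing from above-iso (inside) toward below-iso (outside).
# ---------------------------------------------------------------------------

# corner offsets (x, y, z) in {0,1}^3, corner index 1..8
.mt_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))

# 6 tetrahedra around the main diagonal corner1 -> corner8; each row lists
# 4 corner indices (axis-permutation paths 1 -> 1+e1 -> 1+e1+e2 -> 8)
.mt_tets <- rbind(
  c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
  c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))

#' Extract an iso-surface mesh from a scalar field
#'
#' Marching tetrahedra with linear edge interpolation, in physical
#' micrometre coordinates. Voxels with values strictly greater than `iso`
#' are inside; triangle normals point outward (toward lower values). The
#' field is padded with a below-iso boundary layer, so the mesh is closed
#' even when the inside region touches the array boundary (a flat cap at
#' half a voxel beyond the boundary — mirroring how the commercial tool
#' encloses a surface truncated by the stack top).
#'
#' @param field numeric 3D array (x, y, z).
#' @param iso iso level.
#' @param spacing voxel spacing `c(x, y, z)` in micrometres.
#' @param origin physical position of voxel (1,1,1).
#' @return a `surface_mesh` (empty mesh if the field never exceeds `iso`).
#' @export
marching_tetrahedra <- function(field, iso, spacing = c(1, 1, 1),
                                origin = c(0, 0, 0)) {
  d <- dim(field)
  pad_val <- min(field, iso) - 1
  f <- array(pad_val, d + 2L)
  f[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- field
  dp <- dim(f)
  inside <- f > iso
  if (!any(inside)) {
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  # candidate cubes: any corner differs from corner 1
  nx <- dp[1]; ny <- dp[2]; nz <- dp[3]
  strides <- c(1L, nx, nx * ny)
  corner_off <- as.integer(.mt_corners %*% strides)
  base <- which(array(TRUE, dp - 1L))  # linear over (nx-1, ny-1, nz-1) grid
  bi <- arrayInd(base, dp - 1L)
  base_lin <- (bi[, 1]) + (bi[, 2] - 1L) * nx + (bi[, 3] - 1L) * nx * ny
  in8 <- matrix(FALSE, length(base_lin), 8L)
  for (cc in 1:8) in8[, cc] <- inside[base_lin + corner_off[cc]]
  straddle <- rowSums(in8) %in% 1:7
  base_lin <- base_lin[straddle]
  if (length(base_lin) == 0L)
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  in8 <- in8[straddle, , drop = FALSE]

  # expand to tetrahedra: rows = cube x tet
  tet_corner_lin <- matrix(0L, length(base_lin) * 6L, 4L)
  for (t in 1:6) {
    rows <- (t - 1L) * length(base_lin) + seq_along(base_lin)
    for (j in 1:4) tet_corner_lin[rows, j] <- base_lin + corner_off[.mt_tets[t, j]]
  }
  tin <- matrix(FALSE, nrow(tet_corner_lin), 4L)
  for (j in 1:4) tin[, j] <- inside[tet_corner_lin[, j]]
  case <- tin %*% c(1L, 2L, 4L, 8L)
  keep <- case > 0 & case < 15
  tet_corner_lin <- tet_corner_lin[keep, , drop = FALSE]
  tin <- tin[keep, , drop = FALSE]
  case <- case[keep]

  # per-case triangle recipes: edges as (inside corner, outside corner) pairs
  # within the tet (local corner 1..4); 2-in cases give a quad -> 2 triangles
  one_in <- list(`1` = 1L, `2` = 2L, `4` = 3L, `8` = 4L)
  three_in <- list(`14` = 1L, `13` = 2L, `11` = 3L, `7` = 4L)
  two_in <- list(`3` = c(1L, 2L), `5` = c(1L, 3L), `9` = c(1L, 4L),
                 `6` = c(2L, 3L), `10` = c(2L, 4L), `12` = c(3L, 4L))

  all_a <- list(); all_b <- list()
  for (cs in names(c(one_in, three_in, two_in))) {
    rows <- which(case == as.integer(cs))
    if (!length(rows)) next
    tet_corner_lin_sub <- tet_corner_lin[rows, , drop = FALSE]
    n <- length(rows)
    if (cs %in% names(one_in)) {
      i <- one_in[[cs]]; oth <- setdiff(1:4, i)
      ia <- matrix(i, n, 3); ib <- matrix(oth, n, 3, byrow = TRUE)
      all_a[[length(all_a) + 1L]] <- cbind(
        tet_corner_lin_sub[cbind(1:n, ia[, 1])],
        tet_corner_lin_sub[cbind(1:n, ia[, 2])],
        tet_corner_lin_sub[cbind(1:n, ia[, 3])])
      all_b[[length(all_b) + 1L]] <- cbind(
        tet_corner_lin_sub[cbind(1:n, ib[, 1])],
        tet_corner_lin_sub[cbind(1:n, ib[, 2])],
        tet_corner_lin_sub[cbind(1:n, ib[, 3])])
    } else if (cs %in% names(three_in)) {
      o <- three_in[[cs]]; oth <- setdiff(1:4, o)
      ia <- matrix(oth, n, 3, byrow = TRUE); ib <- matrix(o, n, 3)
      all_a[[length(all_a) + 1L]] <- cbind(
        tet_corner_lin_sub[cbind(1:n, ia[, 1])],
        tet_corner_lin_sub[cbind(1:n, ia[, 2])],
        tet_corner_lin_sub[cbind(1:n, ia[, 3])])
      all_b[[length(all_b) + 1L]] <- cbind(
        tet_corner_lin_sub[cbind(1:n, ib[, 1])],
        tet_corner_lin_sub[cbind(1:n, ib[, 2])],
        tet_corner_lin_sub[cbind(1:n, ib[, 3])])
    } else {
      io <- two_in[[cs]]; i1 <- io[1]; i2 <- io[2]
      oo <- setdiff(1:4, io); o1 <- oo[1]; o2 <- oo[2]
      # quad around: (i1,o1), (i1,o2), (i2,o2), (i2,o1) -> tris 123, 134
      ga <- cbind(rep(i1, n), rep(i1, n), rep(i2, n))   # tri1 inside ends
      gb <- cbind(rep(o1, n), rep(o2, n), rep(o2, n))   # tri1 outside ends
      ha <- cbind(rep(i1, n), rep(i2, n), rep(i2, n))   # tri2
      hb <- cbind(rep(o1, n), rep(o2, n), rep(o1, n))
      all_a[[length(all_a) + 1L]] <- cbind(
        tet_corner_lin_sub[cbind(1:n, ga[, 1])],
        tet_corner_lin_sub[cbind(1:n, ga[, 2])],
        tet_corner_lin_sub[cbind(1:n, ga[, 3])])
      all_b[[length(all_b) + 1L]] <- cbind(
        tet_corner_lin_sub[cbind(1:n, gb[, 1])],
        tet_corner_lin_sub[cbind(1:n, gb[, 2])],
        tet_corner_lin_sub[cbind(1:n, gb[, 3])])
      all_a[[length(all_a) + 1L]] <- cbind(
        tet_corner_lin_sub[cbind(1:n, ha[, 1])],
        tet_corner_lin_sub[cbind(1:n, ha[, 2])],
        tet_corner_lin_sub[cbind(1:n, ha[, 3])])
      all_b[[length(all_b) + 1L]] <- cbind(
        tet_corner_lin_sub[cbind(1:n, hb[, 1])],
        tet_corner_lin_sub[cbind(1:n, hb[, 2])],
        tet_corner_lin_sub[cbind(1:n, hb[, 3])])
    }
  }
  A <- do.call(rbind, all_a)   # n_tri x 3 inside-corner linear index
  B <- do.call(rbind, all_b)   # n_tri x 3 outside-corner linear index

  # unique edge vertices, interpolated along grid edges
  ea <- as.vector(A); eb <- as.vector(B)
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  ua <- ea[uk]; ub <- eb[uk]
  va <- f[ua]; vb <- f[ub]
  tpar <- (iso - va) / (vb - va)
  ai <- arrayInd(ua, dp); bi2 <- arrayInd(ub, dp)
  # padded index -> physical coordinate (padded layer sits one voxel out)
  phys <- function(idx) sweep(sweep(idx - 2, 2, spacing, "*"), 2, origin, "+")
  pa <- phys(ai); pb <- phys(bi2)
  verts <- pa + tpar * (pb - pa)
  tris <- matrix(vid, ncol = 3)

  # orient: normal should point from inside corner centroid toward outside
  a <- verts[tris[, 1], , drop = FALSE]
  b <- verts[tris[, 2], , drop = FALSE]
  c_ <- verts[tris[, 3], , drop = FALSE]
  nrm <- cbind((b - a)[, 2] * (c_ - a)[, 3] - (b - a)[, 3] * (c_ - a)[, 2],
               (b - a)[, 3] * (c_ - a)[, 1] - (b - a)[, 1] * (c_ - a)[, 3],
               (b - a)[, 1] * (c_ - a)[, 2] - (b - a)[, 2] * (c_ - a)[, 1])
  in_cent <- (phys(arrayInd(A[, 1], dp)) + phys(arrayInd(A[, 2], dp)) +
              phys(arrayInd(A[, 3], dp))) / 3
  out_cent <- (phys(arrayInd(B[, 1], dp)) + phys(arrayInd(B[, 2], dp)) +
               phys(arrayInd(B[, 3], dp))) / 3
  flip <- rowSums(nrm * (out_cent - in_cent)) < 0
  tris[flip, ] <- tris[flip, c(1, 3, 2)]

  surface_mesh(verts, tris)
}

#' Reconstruct the organoid surface from the nuclear channel (pass 1)
#'
#' Smooths the nuclear channel at spatial scale `detail_um` (Gaussian with
#' FWHM = `detail_um`), thresholds (Otsu by default), keeps the largest
#' 6-connected component and extracts a triangulated iso-surface in
#' micrometre coordinates. The pass-1 surface may be artificially enclosed
#' where the organoid is truncated by the stack top; run
#' [outside_mask_resurface()] for the corrected pass-2 surface.
#'
#' @param stack a `voxel_stack`.
#' @param channel `"nuclear"` (default) or `"tumor"`.
#' @param detail_um surface detail, micrometres (default 25).
#' @param threshold fixed intensity threshold, or NULL for Otsu.
#' @return a `surface_mesh` with `provenance$pass == 1`.
#' @export
reconstruct_surface <- function(stack, channel = "nuclear", detail_um = 25,
                                threshold = NULL) {
  a <- stack[[channel]]
  sigma_um <- detail_um / 2.355          # FWHM = detail_um
  sm <- smooth_gauss3d(a, sigma_um / stack$spacing)
  if (diff(range(sm)) == 0)
    stopf("empty surface: channel '%s' has uniform intensity", channel)
  t <- threshold %||% otsu_threshold(sm)
  mask <- sm > t
  if (!any(mask))
    stopf("empty surface: no voxels above threshold %g", t)
  comp <- fill_holes(largest_component(mask))
  sm2 <- sm
  sm2[mask & !comp] <- min(sm)           # suppress smaller components
  # interior cavities (patchy nuclear staining) are lifted above the iso
  # level so the surface follows only the outer boundary
  sm2[comp & sm2 <= t] <- t + 1e-3 * (max(sm) - t)
  mesh <- marching_tetrahedra(sm2, t, stack$spacing, stack$origin)
  mesh$provenance <- list(detail_um = detail_um, threshold = t, pass = 1L,
                          inside_mask = comp)
  mesh
}

#' Second-pass surface from an outside mask (pass 2)
#'
#' Builds a channel equal to `fill_value` outside the pass-1 surface and 0
#' inside, extends the organoid cross-section through the stack top (so a
#' surface truncated by the acquisition is continued rather than capped flat
#' at the top image plane), re-smooths at the pass-1 `detail_um`, and
#' re-extracts the surface. The result is watertight with
#' `provenance$pass == 2`.
#'
#' @param stack the `voxel_stack` used for pass 1.
#' @param mesh the pass-1 `surface_mesh` from [reconstruct_surface()].
#' @param fill_value intensity written outside the surface (default 150;
#'   vertex positions are invariant to this choice since the mask is binary).
#' @param smooth_vox anti-aliasing Gaussian sigma, in voxels, applied to the
#'   binary mask before re-extraction. The mask is already smooth at the
#'   pass-1 `detail_um` scale, so only voxel-scale smoothing is needed;
#'   re-smoothing at the full detail scale would shrink high-curvature
#'   surfaces inward by about sigma^2/R.
#' @return a watertight `surface_mesh`.
#' @export
outside_mask_resurface <- function(stack, mesh, fill_value = 150,
                                   smooth_vox = 1.2) {
  inside <- mesh$provenance$inside_mask
  if (is.null(inside) || !any(inside))
    stopf("pass-1 mesh is empty or lacks its inside mask; rerun reconstruct_surface()")
  detail_um <- mesh$provenance$detail_um %||% 25
  d <- dim(inside)
  # indicator field: fill_value inside the organoid, 0 outside
  f_in <- array(0, d)
  f_in[inside] <- fill_value
  # continue the top cross-section upward so the mesh closes above the stack
  # top instead of slamming shut on the top image plane
  n_ext <- ceiling(detail_um / stack$spacing[3]) + 2L
  top <- f_in[, , d[3]]
  if (any(top > 0)) {
    ext <- array(rep(top, n_ext), c(d[1], d[2], n_ext))
    f_in <- array(c(f_in, ext), c(d[1], d[2], d[3] + n_ext))
  }
  smf <- smooth_gauss3d(f_in, rep(smooth_vox, 3))
  m2 <- marching_tetrahedra(smf, fill_value / 2, stack$spacing, stack$origin)
  m2$provenance <- list(detail_um = detail_um, fill_value = fill_value,
                        pass = 2L)
  m2
}

#' Detect tumor cells as spots
#'
#' Scale-matched blob detection: the tumor channel is smoothed with a
#' Gaussian of sigma = diameter / (2*sqrt(3)) per axis (in physical units),
#' and strict 26-neighborhood local maxima above the intensity threshold are
#' reported, with an intensity-weighted sub-voxel centroid refinement.
#'
#' @param stack a `voxel_stack`.
#' @param channel `"tumor"` (default) or `"nuclear"`.
#' @param diameter_um detection size, micrometres (default 10).
#' @param threshold intensity threshold on the smoothed channel, or NULL for
#'   Otsu; an all-background channel yields an empty spot set.
#' @return a `spot_set`: list with `positions` (n x 3, um), `diameter_um`,
#'   `intensities`.
#' @export
detect_spots <- function(stack, channel = "tumor", diameter_um = 10,
                         threshold = NULL) {
  a <- stack[[channel]]
  sigma_um <- diameter_um / (2 * sqrt(3))
  sm <- smooth_gauss3d(a, sigma_um / stack$spacing)
  if (diff(range(sm)) == 0) {
    return(structure(list(positions = matrix(numeric(0), 0, 3,
                                             dimnames = list(NULL, c("x", "y", "z"))),
                          diameter_um = diameter_um,
                          intensities = numeric(0)),
                     class = "spot_set"))
  }
  t <- threshold %||% otsu_threshold(sm)
  d <- dim(sm)
  # strict local maxima over the 26-neighborhood via shifted comparisons
  is_max <- sm > t
  shift_arr <- function(x, s) {
    # shift by s = (sx, sy, sz), padding with -Inf
    out <- array(-Inf, d)
    src <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax]) - s[ax]
      i[i < 1 | i > d[ax]] <- NA
      i
    })
    ok <- lapply(src, function(i) !is.na(i))
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      x[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    if (!any(is_max)) break
    is_max <- is_max & (sm >= shift_arr(sm, c(sx, sy, sz)))
  }
  peaks <- which(is_max)
  # merge plateau maxima and sub-diameter duplicates: greedy suppression by
  # descending intensity with an exclusion radius of half the spot diameter
  if (length(peaks) > 1) {
    pk_um <- sweep(sweep(arrayInd(peaks, d) - 1, 2, stack$spacing, "*"),
                   2, stack$origin, "+")
    ord <- order(sm[peaks], peaks, decreasing = TRUE)
    # exclusion radius: spot scale, but never below the voxel diagonal so
    # symmetric plateau corners cannot double-count one blob
    excl <- max(0.7 * diameter_um, 1.01 * sqrt(sum(stack$spacing^2)))
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) == 0 ||
          min(sqrt(rowSums(sweep(pk_um[kept, , drop = FALSE], 2,
                                 pk_um[i, ])^2))) >= excl) {
        kept <- c(kept, i)
      }
    }
    peaks <- peaks[sort(kept)]
  }
  if (!length(peaks)) {
    return(structure(list(positions = matrix(numeric(0), 0, 3,
                                             dimnames = list(NULL, c("x", "y", "z"))),
                          diameter_um = diameter_um,
                          intensities = numeric(0)),
                     class = "spot_set"))
  }
  pk <- arrayInd(peaks, d)
  # sub-voxel refinement: intensity-weighted centroid over a 3^3 window
  refined <- t(vapply(seq_len(nrow(pk)), function(i) {
    ctr <- pk[i, ]
    rng <- lapply(1:3, function(ax) max(1L, ctr[ax] - 1L):min(d[ax], ctr[ax] + 1L))
    w <- sm[rng[[1]], rng[[2]], rng[[3]]]
    w <- w - min(w)
    if (sum(w) == 0) return(as.numeric(ctr))
    gx <- expand.grid(rng[[1]], rng[[2]], rng[[3]])
    colSums(as.matrix(gx) * as.vector(w)) / sum(w)
  }, numeric(3)))
  pos <- sweep(sweep(refined - 1, 2, stack$spacing, "*"), 2, stack$origin, "+")
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, diameter_um = diameter_um,
                 intensities = sm[peaks]),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d spots (diameter %g um)\n",
              nrow(x$positions), x$diameter_um))
  invisible(x)
}

#' Signed shortest distance of each spot to the organoid surface
#'
#' The open counterpart of the commercial shortest-distance transformation:
#' exact Euclidean distance from each spot to the nearest point on the mesh,
#' signed positive inside (deeper invasion = larger distance) by default.
#'
#' @param spots a `spot_set` (or an n x 3 position matrix).
#' @param mesh a watertight pass-2 `surface_mesh`.
#' @param organoid_id,group labels for the output table.
#' @param sign_convention see [point_mesh_distance()].
#' @return a `data.frame` distance table: `organoid_id`, `group`, `cell_id`,
#'   `x`, `y`, `z`, `distance_um`.
#' @export
shortest_distance <- function(spots, mesh, organoid_id = "org1",
                              group = "control",
                              sign_convention = "inside_positive") {
  pos <- if (inherits(spots, "spot_set")) spots$positions else rbind(spots)
  n <- nrow(pos)
  d <- if (n) point_mesh_distance(pos, mesh, sign_convention) else numeric(0)
  data.frame(
    organoid_id = rep(organoid_id, n), group = rep(group, n),
    cell_id = if (n) paste0(organoid_id, "_s", seq_len(n)) else character(0),
    x = pos[seq_len(n), 1], y = pos[seq_len(n), 2], z = pos[seq_len(n), 3],
    distance_um = d, stringsAsFactors = FALSE)
}
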