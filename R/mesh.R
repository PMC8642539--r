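# Triangle-mesh container and exact point-to-surface geometry.
#
# Meshes live in physical micrometre coordinates. Orientation convention:
# triangle normals point outward, so the signed volume of a closed mesh is
# positive and the signed point distance is positive inside the organoid
# (deeper invasion = larger distance).

#' Construct a triangulated surface mesh
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in micrometres.
#' @param triangles integer matrix (m x 3) of vertex indices (1-based),
#'   ordered counter-clockwise when seen from outside.
#' @param provenance optional list recording how the mesh was built
#'   (e.g. `detail_um`, `threshold`, `pass`).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, provenance = list()) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stopf("triangles must be an m x 3 matrix")
  if (nrow(triangles) > 0 && (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stopf("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               unlist(x$provenance), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Is every edge of the mesh shared by exactly two triangles?
#'
#' @param mesh a `surface_mesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(FALSE)
  e <- rbind(tr[, c(1, 2), drop = FALSE],
             tr[, c(2, 3), drop = FALSE],
             tr[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Surface area of a triangle mesh
#'
#' Sum of triangle areas; defined for open meshes too.
#'
#' @param mesh a `surface_mesh`.
#' @return area in square micrometres.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (nrow(tr) == 0L) return(0)
  a <- v[tr[, 1], , drop = FALSE]
  u <- v[tr[, 2], , drop = FALSE] - a
  w <- v[tr[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

#' Enclosed volume of a watertight mesh
#'
#' Signed tetrahedron sum (divergence theorem); requires a closed mesh.
#'
#' @param mesh a `surface_mesh`.
#' @return volume in cubic micrometres (positive).
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh))
    stopf("mesh is not watertight; volume is undefined (run pass-2 reconstruction)")
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6)) / 6
}

#' Unit icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto a sphere; used as an
#' analytic test surface (exact radius, known volume and area limits).
#'
#' @param radius sphere radius in micrometres.
#' @param subdiv number of 4-to-1 subdivision rounds (0 = icosahedron).
#' @param center length-3 numeric center.
#' @return a `surface_mesh` with outward orientation.
#' @export
icosphere <- function(radius = 1, subdiv = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_key <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      hit <- edge_key[[k]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      idx <- nv + length(newv)
      edge_key[[k]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      i1 <- f[t, 1]; i2 <- f[t, 2]; i3 <- f[t, 3]
      a <- midpoint(i1, i2); b <- midpoint(i2, i3); c_ <- midpoint(i3, i1)
      nf[(t - 1L) * 4L + 1L, ] <- c(i1, a, c_)
      nf[(t - 1L) * 4L + 2L, ] <- c(i2, b, a)
      nf[(t - 1L) * 4L + 3L, ] <- c(i3, c_, b)
      nf[(t - 1L) * 4L + 4L, ] <- c(a, b, c_)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f, provenance = list(kind = "icosphere", radius = radius,
                                       subdiv = subdiv))
}

# Closest points on a set of triangles to a single query point.
# Vectorized barycentric-region algorithm; returns an m x 3 matrix.
closest_point_on_triangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2, p, "+")                       # p - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  m <- nrow(A)
  out <- matrix(NA_real_, m, 3)
  done <- rep(FALSE, m)

  set_rows <- function(idx, pts) {
    out[idx, ] <<- pts
    done[idx] <<- TRUE
  }
  # vertex regions
  r <- !done & d1 <= 0 & d2 <= 0
  if (any(r)) set_rows(which(r), A[r, , drop = FALSE])
  r <- !done & d3 >= 0 & d4 <= d3
  if (any(r)) set_rows(which(r), B[r, , drop = FALSE])
  r <- !done & d6 >= 0 & d5 <= d6
  if (any(r)) set_rows(which(r), C[r, , drop = FALSE])
  # edge AB
  vc <- d1 * d4 - d3 * d2
  r <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(r)) {
    w <- d1[r] / (d1[r] - d3[r])
    set_rows(which(r), A[r, , drop = FALSE] + w * ab[r, , drop = FALSE])
  }
  # edge AC
  vb <- d5 * d2 - d1 * d6
  r <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(r)) {
    w <- d2[r] / (d2[r] - d6[r])
    set_rows(which(r), A[r, , drop = FALSE] + w * ac[r, , drop = FALSE])
  }
  # edge BC
  va <- d3 * d6 - d5 * d4
  r <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(r)) {
    w <- (d4[r] - d3[r]) / ((d4[r] - d3[r]) + (d5[r] - d6[r]))
    set_rows(which(r), B[r, , drop = FALSE] +
               w * (C[r, , drop = FALSE] - B[r, , drop = FALSE]))
  }
  # face interior
  r <- !done
  if (any(r)) {
    denom <- va[r] + vb[r] + vc[r]
    vv <- vb[r] / denom; ww <- vc[r] / denom
    set_rows(which(r), A[r, , drop = FALSE] +
               vv * ab[r, , drop = FALSE] + ww * ac[r, , drop = FALSE])
  }
  out
}

#' Generalized winding number of points with respect to a mesh
#'
#' Sum of signed solid angles divided by 4*pi; approximately 1 for points
#' inside a closed outward-oriented mesh and 0 outside.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a `surface_mesh`.
#' @return numeric vector of winding numbers.
#' @export
winding_number <- function(points, mesh) {
  points <- rbind(points)
  v <- mesh$vertices; tr <- mesh$triangles
  A <- v[tr[, 1], , drop = FALSE]
  B <- v[tr[, 2], , drop = FALSE]
  C <- v[tr[, 3], , drop = FALSE]
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    a <- sweep(A, 2, p); b <- sweep(B, 2, p); c_ <- sweep(C, 2, p)
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c_^2))
    num <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
           a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
           a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(b * c_) * la +
           rowSums(c_ * a) * lb
    sum(2 * atan2(num, den)) / (4 * pi)
  }, numeric(1))
}

#' Ray-parity inside test
#'
#' Casts a ray along +z from each point and counts triangle crossings; an odd
#' count means inside. Kept as an independent cross-check of
#' [winding_number()].
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a `surface_mesh`.
#' @return logical vector, TRUE = inside.
#' @export
ray_parity_inside <- function(points, mesh) {
  points <- rbind(points)
  v <- mesh$vertices; tr <- mesh$triangles
  A <- v[tr[, 1], , drop = FALSE]
  B <- v[tr[, 2], , drop = FALSE]
  C <- v[tr[, 3], , drop = FALSE]
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    # 2D barycentric test in the xy-plane
    d <- (B[, 2] - C[, 2]) * (A[, 1] - C[, 1]) +
         (C[, 1] - B[, 1]) * (A[, 2] - C[, 2])
    l1 <- ((B[, 2] - C[, 2]) * (p[1] - C[, 1]) +
           (C[, 1] - B[, 1]) * (p[2] - C[, 2])) / d
    l2 <- ((C[, 2] - A[, 2]) * (p[1] - C[, 1]) +
           (A[, 1] - C[, 1]) * (p[2] - C[, 2])) / d
    l3 <- 1 - l1 - l2
    hit <- is.finite(l1) & l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(hit)) return(FALSE)
    zhit <- l1[hit] * A[hit, 3] + l2[hit] * B[hit, 3] + l3[hit] * C[hit, 3]
    sum(zhit > p[3]) %% 2L == 1L
  }, logical(1))
}

#' Signed shortest distance from points to a watertight mesh
#'
#' Exact Euclidean distance to the nearest point on any triangle (vertex,
#' edge and face cases all handled), signed positive inside the closed mesh.
#' A vertex-distance bound prunes the candidate triangles before the exact
#' closest-point evaluation.
#'
#' @param points n x 3 matrix of query points (micrometres).
#' @param mesh a watertight `surface_mesh`.
#' @param sign_convention `"inside_positive"` (default) or
#'   `"outside_positive"`.
#' @return numeric vector of signed distances in micrometres.
#' @export
point_mesh_distance <- function(points, mesh,
                                sign_convention = c("inside_positive",
                                                    "outside_positive")) {
  sign_convention <- match.arg(sign_convention)
  if (!is_watertight(mesh))
    stopf("mesh is open; signed distance needs a watertight (pass-2) surface")
  points <- rbind(points)
  v <- mesh$vertices; tr <- mesh$triangles
  A <- v[tr[, 1], , drop = FALSE]
  B <- v[tr[, 2], , drop = FALSE]
  C <- v[tr[, 3], , drop = FALSE]
  e1 <- sqrt(rowSums((B - A)^2)); e2 <- sqrt(rowSums((C - B)^2))
  e3 <- sqrt(rowSums((A - C)^2))
  max_edge <- max(e1, e2, e3)

  d <- vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    dv <- sqrt((v[, 1] - p[1])^2 + (v[, 2] - p[2])^2 + (v[, 3] - p[3])^2)
    ub <- min(dv)
    # a triangle can only beat ub if one of its corners is within ub + edge
    corner_min <- pmin(dv[tr[, 1]], dv[tr[, 2]], dv[tr[, 3]])
    cand <- which(corner_min <= ub + max_edge)
    cp <- closest_point_on_triangles(p, A[cand, , drop = FALSE],
                                     B[cand, , drop = FALSE],
                                     C[cand, , drop = FALSE])
    min(sqrt(rowSums(sweep(cp, 2, p)^2)))
  }, numeric(1))

  inside <- abs(winding_number(points, mesh)) > 0.5
  s <- ifelse(inside, 1, -1)
  if (sign_convention == "outside_positive") s <- -s
  s * d
}

#' Write a mesh to Wavefront OBJ or ASCII PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output file; format chosen by extension (`.obj` or `.ply`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; tr <- mesh$triangles
  if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(tr)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  } else stopf("unsupported mesh format '%s' (use .obj or .ply)", ext)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' @param path OBJ file written by [write_mesh()] (triangular faces).
#' @return a `surface_mesh`.
#' @export
read_mesh_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(vapply(strsplit(x[2:4], "/"), `[[`, "", 1L))
  }))
  surface_mesh(v, f, provenance = list(source = path))
}
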