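# Triangle-mesh support: surface extraction from a binary voxel volume,
# per-face normals, watertightness checks, voxelization of a closed mesh, and
# minimal ASCII STL read/write. The chamber model keeps both representations
# (mesh for edge rendering, voxel indicator for shadow/CADE) in sync.

# shift a 3D logical array by one voxel along axis (+1/-1), padding with FALSE
shift3 <- function(A, axis, by) {
  d <- dim(A)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  if (by > 0) { idx_dst[[axis]] <- 2:d[axis];        idx_src[[axis]] <- 1:(d[axis] - 1) }
  else        { idx_dst[[axis]] <- 1:(d[axis] - 1);  idx_src[[axis]] <- 2:d[axis] }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <- A[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Make a binary volume well-composed in the edge sense: remove 2x2 checkerboard
# configurations in every axis-aligned slice plane by filling one of the two
# empty diagonal cells. Filling is monotone (only adds voxels) so the loop
# terminates; the cuberille surface of a well-composed set is edge-manifold.
make_well_composed <- function(A) {
  d <- dim(A)
  repeat {
    changed <- FALSE
    for (ax_pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      i <- ax_pair[1]; j <- ax_pair[2]
      n_i <- d[i]; n_j <- d[j]
      # windows [p, p+1] x [q, q+1] in the (i, j) plane
      sl <- function(di, dj) {
        idx <- lapply(d, seq_len)
        idx[[i]] <- (1 + di):(n_i - 1 + di)
        idx[[j]] <- (1 + dj):(n_j - 1 + dj)
        A[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      }
      a00 <- sl(0, 0); a11 <- sl(1, 1); a10 <- sl(1, 0); a01 <- sl(0, 1)
      bad <- (a00 & a11 & !a10 & !a01) | (!a00 & !a11 & a10 & a01)
      if (any(bad)) {
        changed <- TRUE
        w <- which(bad, arr.ind = TRUE)
        # fill the (+i, 0j) corner of diag type 1, the (0i, 0j) corner of type 2
        filled <- (a00 & a11)[bad]
        w[, i] <- w[, i] + ifelse(filled, 1L, 0L)
        A[w] <- TRUE
      }
    }
    if (!changed) break
  }
  A
}

# Cuberille surface extraction: every boundary voxel face becomes two
# triangles with outward orientation. `origin` is the world position of the
# centre of voxel (1,1,1); `spacing` the isotropic voxel size in mm.
# Vertices sit on the corner grid (voxel centres +/- spacing/2).
extract_surface <- function(A, spacing, origin) {
  d <- dim(A)
  nc <- d + 1L                                  # corner-grid extents
  corner_id <- function(i, j, k) (i - 1L) + nc[1] * ((j - 1L) + nc[2] * (k - 1L)) + 1L

  tri_v1 <- integer(0); tri_v2 <- integer(0); tri_v3 <- integer(0)
  face_normal <- NULL
  add_faces <- function(vox, axis, sgn) {
    # vox: n x 3 voxel indices with an exposed face on side `sgn` of `axis`
    if (nrow(vox) == 0) return()
    i <- vox[, 1]; j <- vox[, 2]; k <- vox[, 3]
    # corner offsets of the exposed face, ordered counter-clockwise seen from
    # outside (right-hand rule -> outward normal)
    offs <- switch(axis,
      `1` = if (sgn > 0) list(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1))
            else         list(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0)),
      `2` = if (sgn > 0) list(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0))
            else         list(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1)),
      `3` = if (sgn > 0) list(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
            else         list(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0)))
    ids <- lapply(offs, function(o) corner_id(i + o[1], j + o[2], k + o[3]))
    n <- length(i)
    nrm <- matrix(0, 2 * n, 3); nrm[, axis] <- sgn
    tri_v1 <<- c(tri_v1, ids[[1]], ids[[1]])
    tri_v2 <<- c(tri_v2, ids[[2]], ids[[3]])
    tri_v3 <<- c(tri_v3, ids[[3]], ids[[4]])
    face_normal <<- rbind(face_normal, nrm)
  }
  for (axis in 1:3) for (sgn in c(1L, -1L)) {
    exposed <- A & !shift3(A, axis, -sgn)       # neighbour on side sgn empty
    add_faces(which(exposed, arr.ind = TRUE), axis, sgn)
  }

  used <- sort(unique(c(tri_v1, tri_v2, tri_v3)))
  remap <- integer(prod(nc)); remap[used] <- seq_along(used)
  faces <- cbind(remap[tri_v1], remap[tri_v2], remap[tri_v3])
  u0 <- used - 1L
  ci <- u0 %% nc[1]; rest <- u0 %/% nc[1]
  cj <- rest %% nc[2]; ck <- rest %/% nc[2]
  # corner (0,0,0) of voxel (1,1,1) lies at origin - spacing/2
  verts <- cbind(origin[1] + (ci - 0.5) * spacing,
                 origin[2] + (cj - 0.5) * spacing,
                 origin[3] + (ck - 0.5) * spacing)
  triangle_mesh(verts, faces, normals = face_normal)
}

#' Triangle mesh
#'
#' @param vertices N x 3 numeric matrix of vertex positions (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices, oriented
#'   counter-clockwise seen from outside.
#' @param normals Optional M x 3 matrix of outward unit face normals; computed
#'   from the face windings when omitted.
#' @return Object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (is.null(normals)) normals <- geometric_face_normals(vertices, faces)
  structure(list(vertices = vertices, faces = faces, normals = as.matrix(normals)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

geometric_face_normals <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  zero <- len < 1e-12
  if (any(zero)) { la_log_bump("degenerate_triangles", sum(zero)); len[zero] <- 1 }
  n / len
}

face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

face_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(n^2)) / 2
}

#' Check that a mesh is closed (watertight)
#'
#' A closed orientable surface has every undirected edge shared by exactly two
#' faces.
#'
#' @param mesh A [triangle_mesh()].
#' @return `TRUE` if every edge is shared by exactly 2 faces.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# Replace axis-aligned cuberille normals by the (outward) gradient of a
# Gaussian-smoothed copy of the indicator volume, sampled at each face
# centroid. Gives the smooth normal field an apparent-edge renderer needs.
smooth_mesh_normals <- function(mesh, A, spacing, origin, sigma_vox = 1.5) {
  S <- gauss_smooth3(A * 1.0, sigma_vox)
  d <- dim(A)
  # central-difference gradient, voxel units
  g <- list()
  for (ax in 1:3) {
    plus <- shift3_num(S, ax, +1); minus <- shift3_num(S, ax, -1)
    g[[ax]] <- (plus - minus) / 2
  }
  ctr <- face_centroids(mesh)
  # nearest-voxel sampling of the gradient at the centroid
  idx <- sapply(1:3, function(ax) {
    pmin(pmax(round((ctr[, ax] - origin[ax]) / spacing) + 1, 1), d[ax])
  })
  lin <- idx[, 1] + d[1] * ((idx[, 2] - 1) + d[2] * (idx[, 3] - 1))
  G <- cbind(g[[1]][lin], g[[2]][lin], g[[3]][lin])
  len <- sqrt(rowSums(G^2))
  ok <- len > 1e-8
  N <- mesh$normals
  N[ok, ] <- -G[ok, ] / len[ok]                 # gradient points inward
  mesh$normals <- N
  mesh
}

# numeric shift with replicate padding
shift3_num <- function(A, axis, by) {
  d <- dim(A)
  idx <- lapply(d, seq_len)
  src <- idx
  src[[axis]] <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
  A[src[[1]], src[[2]], src[[3]], drop = FALSE]
}

# separable 3D Gaussian smoothing via banded matrix products
gauss_smooth3 <- function(A, sigma) {
  d <- dim(A)
  K <- lapply(d, function(n) gauss_matrix(n, sigma))
  X <- matrix(A, d[1])                       # d1 x (d2 d3)
  X <- K[[1]] %*% X
  A <- array(X, d)
  A <- aperm(A, c(2, 1, 3))
  X <- K[[2]] %*% matrix(A, d[2])
  A <- aperm(array(X, d[c(2, 1, 3)]), c(2, 1, 3))
  A <- aperm(A, c(3, 2, 1))
  X <- K[[3]] %*% matrix(A, d[3])
  aperm(array(X, d[c(3, 2, 1)]), c(3, 2, 1))
}

# n x n 1-D Gaussian convolution matrix with reflect padding
gauss_matrix <- function(n, sigma, deriv = FALSE) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- if (deriv) -x / sigma^2 * k / sum(exp(-x^2 / (2 * sigma^2)))
       else k / sum(k)
  M <- matrix(0, n, n)
  for (ii in seq_len(n)) {
    j <- ii + x
    # reflect indices (mirror without repeating the border sample)
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    for (m in seq_along(j)) M[ii, j[m]] <- M[ii, j[m]] + k[m]
  }
  M
}

#' Write a triangle mesh as ASCII STL
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output file path.
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$normals
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid atriareg", con)
  tri <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    N[, 1], N[, 2], N[, 3],
    V[F[, 1], 1], V[F[, 1], 2], V[F[, 1], 3],
    V[F[, 2], 1], V[F[, 2], 2], V[F[, 2], 3],
    V[F[, 3], 1], V[F[, 3], 2], V[F[, 3], 3])
  writeLines(tri, con)
  writeLines("endsolid atriareg", con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Vertices repeated across facets are merged by exact coordinate match.
#'
#' @param path STL file path.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  vx <- grep("^\\s*vertex", lines, value = TRUE)
  nm <- grep("^\\s*facet normal", lines, value = TRUE)
  if (length(vx) == 0 || length(vx) %% 3 != 0) stop("malformed ASCII STL: ", path)
  parse3 <- function(s, skip) {
    t(vapply(strsplit(trimws(s), "\\s+"), function(p) as.numeric(p[(skip + 1):(skip + 3)]),
             numeric(3)))
  }
  P <- parse3(vx, 1L)
  N <- parse3(nm, 2L)
  key <- paste(P[, 1], P[, 2], P[, 3])
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  verts <- P[uk, , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces, normals = N)
}

# Voxelize a closed mesh on a grid by parity ray casting along +z through each
# (x, y) column of voxel centres.
voxelize_mesh <- function(mesh, spacing, grid_shape, origin) {
  if (!is_watertight(mesh))
    stop("mesh is not watertight (an edge is not shared by exactly 2 faces); refusing to voxelize")
  d <- as.integer(grid_shape)
  A <- array(FALSE, d)
  V <- mesh$vertices; F <- mesh$faces
  xs <- origin[1] + (seq_len(d[1]) - 1) * spacing
  ys <- origin[2] + (seq_len(d[2]) - 1) * spacing
  zs <- origin[3] + (seq_len(d[3]) - 1) * spacing
  # per-column z crossings, accumulated triangle by triangle
  crossings <- vector("list", d[1] * d[2])
  eps <- 1e-9
  for (f in seq_len(nrow(F))) {
    p1 <- V[F[f, 1], ]; p2 <- V[F[f, 2], ]; p3 <- V[F[f, 3], ]
    xr <- range(p1[1], p2[1], p3[1]); yr <- range(p1[2], p2[2], p3[2])
    ix <- which(xs >= xr[1] - eps & xs <= xr[2] + eps)
    iy <- which(ys >= yr[1] - eps & ys <= yr[2] + eps)
    if (!length(ix) || !length(iy)) next
    for (i in ix) for (j in iy) {
      # 2D point-in-triangle (xy), then z of the plane at that point
      x <- xs[i]; y <- ys[j]
      d1 <- (p2[1] - p1[1]) * (y - p1[2]) - (p2[2] - p1[2]) * (x - p1[1])
      d2 <- (p3[1] - p2[1]) * (y - p2[2]) - (p3[2] - p2[2]) * (x - p2[1])
      d3 <- (p1[1] - p3[1]) * (y - p3[2]) - (p1[2] - p3[2]) * (x - p3[1])
      # half-open rule: count edges on one side only to avoid double counting
      inside <- (d1 > eps & d2 > eps & d3 > eps) | (d1 < -eps & d2 < -eps & d3 < -eps)
      if (!inside) next
      n <- cross3(p2 - p1, p3 - p1)
      if (abs(n[3]) < 1e-12) next
      z <- p1[3] - (n[1] * (x - p1[1]) + n[2] * (y - p1[2])) / n[3]
      k <- (i - 1) + d[1] * (j - 1) + 1
      crossings[[k]] <- c(crossings[[k]], z)
    }
  }
  for (k in seq_along(crossings)) {
    cz <- crossings[[k]]
    if (is.null(cz) || length(cz) < 2) next
    cz <- sort(cz)
    i <- (k - 1) %% d[1] + 1
    j <- (k - 1) %/% d[1] + 1
    for (m in seq(1, length(cz) - 1, by = 2)) {
      kk <- which(zs > cz[m] & zs < cz[m + 1])
      if (length(kk)) A[i, j, kk] <- TRUE
    }
  }
  A
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
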