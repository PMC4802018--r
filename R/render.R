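# Renderers consumed by the similarity measures: the projected binary shadow
# S_T of the transformed model, the apparent-edge image E_T rendered from the
# surface mesh with opacity 1 - |d.n|, and the contrast-agent distribution
# estimate (CADE) C_T^3D with its two forward projections.

# focal length in pixels recovered from a 3x4 projection matrix (zero skew):
# f_px = |m1 x m3| / |m3|^2 where m_i are the rows of the left 3x3 block.
focal_px <- function(P) {
  m1 <- P[1, 1:3]; m3 <- P[3, 1:3]
  sqrt(sum(cross3(m1, m3)^2)) / sum(m3^2)
}

# per-point projected extent (px) of a cube of side voxel_mm at depths w
projected_size_px <- function(P, w, voxel_mm) {
  voxel_mm * focal_px(P) / pmax(abs(w), 1e-6)
}

# Splat points into the raster. Each point covers a square footprint of
# ceil(projected size) pixels (min 1). Returns either per-pixel counts
# (`counts = TRUE`) or the unique 0-based linear indices of covered pixels.
splat_points <- function(P, pts, shp, voxel_mm, counts = FALSE) {
  if (nrow(pts) == 0) {
    return(if (counts) matrix(0, shp[1], shp[2]) else integer(0))
  }
  pr <- project_points(P, pts)
  size_px <- pmax(1L, as.integer(ceiling(projected_size_px(P, pr$w, voxel_mm))))
  u <- as.integer(round(pr$u)); v <- as.integer(round(pr$v))
  npix <- shp[1] * shp[2]
  acc <- if (counts) numeric(npix) else NULL
  hit <- if (!counts) logical(npix) else NULL
  for (s in sort(unique(size_px))) {
    sel <- size_px == s
    offs <- seq.int(-((s - 1L) %/% 2L), s %/% 2L)
    us <- u[sel]; vs <- v[sel]
    for (du in offs) for (dv in offs) {
      uu <- us + du; vv <- vs + dv
      ok <- uu >= 0L & uu < shp[2] & vv >= 0L & vv < shp[1]
      if (!any(ok)) next
      idx <- vv[ok] + 1L + uu[ok] * shp[1]
      if (counts) acc <- acc + tabulate(idx, nbins = npix)
      else hit[idx] <- TRUE
    }
  }
  if (counts) matrix(acc, shp[1], shp[2]) else which(hit)
}

#' Render the projected shadow of the model
#'
#' A pixel is set iff at least one inside-chamber voxel, translated by `T`,
#' splats onto it; each voxel covers its projected square footprint so the
#' shadow has no pinholes when voxels are coarser than pixels.
#'
#' @param model An [atrium_model()].
#' @param P 3x4 projection matrix.
#' @param T A [rigid_transform()] or length-3 translation (mm).
#' @param image_shape `(rows, cols)`; defaults to the geometry used to build
#'   the projection matrix must be supplied by the caller.
#' @return Binary matrix (0/1) of the shadow.
#' @export
render_shadow <- function(model, P, T, image_shape) {
  t <- as_translation(T)
  pts <- sweep(model_voxel_centers(model), 2, t, "+")
  idx <- splat_points(P, pts, image_shape, model$spacing)
  S <- matrix(0, image_shape[1], image_shape[2])
  S[idx] <- 1
  S
}

# internal fast path: 0-based... returns 1-based linear pixel indices of the
# shadow, given precomputed camera-frame voxel projections (see eval context)
shadow_indices <- function(ctx_plane, t, shp) {
  pr <- ctx_plane$project(t)
  size_px <- pmax(1L, as.integer(ceiling(ctx_plane$fpx * ctx_plane$voxel_mm /
                                           pmax(abs(pr$w), 1e-6))))
  u <- as.integer(round(pr$u)); v <- as.integer(round(pr$v))
  npix <- shp[1] * shp[2]
  hit <- logical(npix)
  for (s in sort(unique(size_px))) {
    sel <- size_px == s
    offs <- seq.int(-((s - 1L) %/% 2L), s %/% 2L)
    us <- u[sel]; vs <- v[sel]
    for (du in offs) for (dv in offs) {
      uu <- us + du; vv <- vs + dv
      ok <- uu >= 0L & uu < shp[2] & vv >= 0L & vv < shp[1]
      if (any(ok)) hit[vv[ok] + 1L + uu[ok] * shp[1]] <- TRUE
    }
  }
  which(hit)
}

#' Opacity of a surface element seen along a viewing direction
#'
#' Surface patches parallel to the detector (normal along the ray) are
#' transparent; patches seen edge-on are opaque.
#'
#' @param d Unit viewing direction (source to surface point).
#' @param n Unit surface normal.
#' @return `1 - |d . n|`.
#' @export
triangle_opacity <- function(d, n) 1 - abs(sum(d * n))

#' Render the apparent-edge image of a mesh
#'
#' Every triangle contributes opacity `o = 1 - |d . n|`, where `d` is the unit
#' direction from the X-ray source to the triangle centroid and `n` its
#' outward normal; contributions composite order-independently as
#' `1 - prod(1 - o)`. Triangles are deposited over their projected footprint
#' (they are small compared to the pixel raster for voxel-derived meshes).
#' The result is optionally Gaussian-smoothed so it is comparable to the
#' derivative-of-Gaussian edge image of the fluoroscopic frames.
#'
#' @param mesh A [triangle_mesh()] with outward unit normals.
#' @param P 3x4 projection matrix.
#' @param T A [rigid_transform()] or length-3 translation (mm).
#' @param image_shape `(rows, cols)`.
#' @param smooth_sigma Gaussian scale in px (0 = no smoothing).
#' @return Non-negative matrix `E_T`.
#' @export
render_apparent_edges <- function(mesh, P, T, image_shape, smooth_sigma = 0) {
  t <- as_translation(T)
  areas <- face_areas(mesh)
  keep <- areas > 1e-12
  if (!all(keep)) la_log_bump("degenerate_triangles", sum(!keep))
  ctr <- sweep(face_centroids(mesh)[keep, , drop = FALSE], 2, t, "+")
  nrm <- mesh$normals[keep, , drop = FALSE]
  src <- camera_center(P)
  E <- edge_deposit(P, src, ctr, nrm, image_shape,
                    tri_size_mm = sqrt(2 * areas[keep]))
  if (smooth_sigma > 0) E <- gauss_blur2(E, smooth_sigma)
  E
}

# shared deposit step (also used by the cached eval context)
edge_deposit <- function(P, src, ctr, nrm, shp, tri_size_mm) {
  d <- sweep(ctr, 2, src, "-")
  d <- d / sqrt(rowSums(d^2))
  o <- 1 - abs(rowSums(d * nrm))
  o <- pmin(o, 1 - 1e-9)
  pr <- project_points(P, ctr)
  size_px <- pmax(1L, as.integer(ceiling(tri_size_mm * focal_px(P) /
                                           pmax(abs(pr$w), 1e-6))))
  u <- as.integer(round(pr$u)); v <- as.integer(round(pr$v))
  npix <- shp[1] * shp[2]
  l1mo <- log1p(-o)
  all_idx <- vector("list", 0); all_val <- vector("list", 0)
  for (s in sort(unique(size_px))) {
    sel <- size_px == s
    offs <- seq.int(-((s - 1L) %/% 2L), s %/% 2L)
    us <- u[sel]; vs <- v[sel]; ls <- l1mo[sel]
    for (du in offs) for (dv in offs) {
      uu <- us + du; vv <- vs + dv
      ok <- uu >= 0L & uu < shp[2] & vv >= 0L & vv < shp[1]
      if (!any(ok)) next
      all_idx[[length(all_idx) + 1L]] <- vv[ok] + 1L + uu[ok] * shp[1]
      all_val[[length(all_val) + 1L]] <- ls[ok]
    }
  }
  if (!length(all_idx)) return(matrix(0, shp[1], shp[2]))
  # sparseMatrix sums duplicate entries in C: a weighted bincount
  sm <- Matrix::sparseMatrix(i = unlist(all_idx), j = rep(1L, length(unlist(all_idx))),
                             x = unlist(all_val), dims = c(npix, 1L))
  matrix(1 - exp(as.numeric(sm)), shp[1], shp[2])
}

# separable 2D Gaussian blur with reflect padding (banded-matrix form);
# the banded convolution matrices are cached per (size, sigma)
.gauss_cache <- new.env(parent = emptyenv())

gauss_matrix_sparse <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  if (!is.null(.gauss_cache[[key]])) return(.gauss_cache[[key]])
  M <- methods::as(Matrix::Matrix(gauss_matrix(n, sigma), sparse = TRUE), "generalMatrix")
  .gauss_cache[[key]] <- M
  M
}

gauss_blur2 <- function(X, sigma) {
  Kr <- gauss_matrix_sparse(nrow(X), sigma)
  Kc <- gauss_matrix_sparse(ncol(X), sigma)
  as.matrix(Kr %*% X %*% Matrix::t(Kc))
}

#' Contrast-agent distribution estimate (CADE)
#'
#' A voxel of the chamber is estimated as contrasted iff (a) it projects onto
#' a contrasted pixel in plane A, (b) onto a contrasted pixel in plane B, and
#' (c) it lies inside the chamber:
#' `C3D(v) = I_thr_A(P_A(T(v))) * I_thr_B(P_B(T(v))) * chi(v)`
#' with nearest-pixel lookup; voxels projecting outside either image count as
#' uncontrasted. The 2D validations `C_A`, `C_B` are formed by splatting all
#' contrasted voxels back into each plane.
#'
#' @param model An [atrium_model()].
#' @param I_thr_A,I_thr_B Binary matrices (thresholded contrast masks).
#' @param geometry A [projection_geometry()].
#' @param T A [rigid_transform()] or length-3 translation (mm).
#' @return Object of class `cade_result`: `C3D` (logical array on the model
#'   grid), `C_A`, `C_B` (binary matrices).
#' @export
compute_cade <- function(model, I_thr_A, I_thr_B, geometry, T) {
  t <- as_translation(T)
  shp <- geometry$image_shape
  stopifnot(all(dim(I_thr_A) == shp), all(dim(I_thr_B) == shp))
  pts <- sweep(model_voxel_centers(model), 2, t, "+")
  keep <- lookup_binary(geometry$P_A, pts, I_thr_A) &
          lookup_binary(geometry$P_B, pts, I_thr_B)
  C3D <- array(FALSE, dim(model$volume))
  C3D[which(model$volume)[keep]] <- TRUE
  sub <- pts[keep, , drop = FALSE]
  mk <- function(P) {
    idx <- splat_points(P, sub, shp, model$spacing)
    M <- matrix(0, shp[1], shp[2]); M[idx] <- 1; M
  }
  structure(list(C3D = C3D, C_A = mk(geometry$P_A), C_B = mk(geometry$P_B)),
            class = "cade_result")
}

# nearest-pixel binary lookup; outside-image -> FALSE
lookup_binary <- function(P, pts, I) {
  pr <- project_points(P, pts)
  u <- as.integer(round(pr$u)); v <- as.integer(round(pr$v))
  ok <- u >= 0L & u < ncol(I) & v >= 0L & v < nrow(I) & pr$w > 0
  out <- logical(length(u))
  out[ok] <- I[cbind(v[ok] + 1L, u[ok] + 1L)] > 0
  out
}
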