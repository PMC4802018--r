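#' Biplane projection geometry
#'
#' Bundles the two 3x4 projection matrices of a biplane C-arm system together
#' with the detector raster. Each matrix maps homogeneous world coordinates in
#' millimetres to homogeneous pixel coordinates `(u, v, w)`; pixel coordinates
#' are 0-based with pixel centres at integers, `u` along image columns and `v`
#' along image rows.
#'
#' @param P_A,P_B 3x4 numeric projection matrices for the A and B plane.
#' @param image_shape Integer pair `(rows, cols)` of the detector raster.
#' @param pixel_spacing Detector pixel spacing in mm (isotropic).
#' @return An object of class `projection_geometry` with the matrices, the
#'   raster description and the derived camera centres (`source_A`,
#'   `source_B`, world mm).
#' @seealso [make_biplane_geometry()] for a parametric C-arm setup.
#' @export
projection_geometry <- function(P_A, P_B, image_shape, pixel_spacing = 1) {
  P_A <- as.matrix(P_A); P_B <- as.matrix(P_B)
  for (P in list(P_A, P_B)) {
    if (!all(dim(P) == c(3L, 4L))) stop("projection matrices must be 3x4")
    if (qr(P)$rank < 3L) stop("projection matrix must have rank 3")
  }
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L))
    stop("image_shape must be (rows, cols)")
  src_A <- camera_center(P_A)
  src_B <- camera_center(P_B)
  dir_A <- principal_direction(P_A)
  dir_B <- principal_direction(P_B)
  if (abs(abs(sum(dir_A * dir_B)) - 1) < 1e-8)
    stop("principal rays of the two planes must not be parallel")
  structure(list(
    P_A = P_A, P_B = P_B,
    image_shape = image_shape, pixel_spacing = pixel_spacing,
    source_A = src_A, source_B = src_B
  ), class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry> %d x %d px, %.3f mm/px\n",
              x$image_shape[1], x$image_shape[2], x$pixel_spacing))
  cat(sprintf("  source A: (%.1f, %.1f, %.1f) mm\n", x$source_A[1], x$source_A[2], x$source_A[3]))
  cat(sprintf("  source B: (%.1f, %.1f, %.1f) mm\n", x$source_B[1], x$source_B[2], x$source_B[3]))
  invisible(x)
}

# camera centre: right null vector of P, dehomogenized
camera_center <- function(P) {
  M <- P[, 1:3]; p4 <- P[, 4]
  as.numeric(solve(M, -p4))
}

# unit vector of the principal ray (camera z-axis), pointing away from the source
principal_direction <- function(P) {
  m3 <- P[3, 1:3]
  d <- m3 / sqrt(sum(m3^2))
  # sign: det(M) > 0 keeps d pointing from source towards the scene
  if (det(P[, 1:3]) < 0) d <- -d
  d
}

#' Construct a parametric biplane C-arm geometry
#'
#' Builds two pinhole cameras rotated about the patient's cranio-caudal (z)
#' axis, both focused on the world origin (the iso-center). World coordinates:
#' x to the patient's left, y posterior, z cranial. The default angles give a
#' frontal (AP) A-plane and a lateral B-plane, the typical configuration for
#' left-atrial angiography.
#'
#' @param image_shape `(rows, cols)` of the detector raster.
#' @param detector_width_mm Physical detector width in mm; the pixel spacing is
#'   `detector_width_mm / cols` so pixel-unit parameters scale with resolution.
#' @param sid Source-to-detector distance in mm.
#' @param sod Source-to-iso-center distance in mm.
#' @param angle_A,angle_B Rotation of each camera about the z axis, degrees.
#' @return A [projection_geometry()].
#' @export
make_biplane_geometry <- function(image_shape = c(256L, 256L),
                                  detector_width_mm = 315.4,
                                  sid = 1200, sod = 750,
                                  angle_A = 0, angle_B = 90) {
  image_shape <- as.integer(image_shape)
  ps <- detector_width_mm / image_shape[2]
  make_P <- function(theta_deg) {
    th <- theta_deg * pi / 180
    d  <- c(-sin(th), cos(th), 0)           # principal ray, source -> iso-center
    xc <- c(cos(th), sin(th), 0)            # image u axis in world
    yc <- c(0, 0, -1)                       # image v axis (rows grow caudally -> -z)
    src <- -sod * d
    R <- rbind(xc, yc, d)
    K <- rbind(c(sid / ps, 0, (image_shape[2] - 1) / 2),
               c(0, sid / ps, (image_shape[1] - 1) / 2),
               c(0, 0, 1))
    unname(K %*% cbind(R, -R %*% src))
  }
  projection_geometry(make_P(angle_A), make_P(angle_B), image_shape, ps)
}

#' Project a world point through a projection matrix
#'
#' Applies the 3x4 matrix to the homogeneous world point and performs the
#' perspective division.
#'
#' @param P 3x4 projection matrix.
#' @param x World point, length-3 numeric (mm).
#' @return Pixel coordinate `(u, v)` (0-based, pixel centres at integers).
#' @export
project_point <- function(P, x) {
  h <- as.numeric(P %*% c(x, 1))
  if (abs(h[3]) < .Machine$double.eps)
    stop("point projects to infinity (homogeneous w = 0)")
  h[1:2] / h[3]
}

# vectorized projection: X is N x 3; returns list(u, v, w) of length-N vectors
project_points <- function(P, X) {
  H <- X %*% t(P[, 1:3])
  H <- sweep(H, 2, P[, 4], "+")
  list(u = H[, 1] / H[, 3], v = H[, 2] / H[, 3], w = H[, 3])
}

#' Back-project a pixel to its viewing ray
#'
#' @param P 3x4 projection matrix.
#' @param uv Pixel coordinate `(u, v)`.
#' @return List with `origin` (the camera centre, mm) and unit `direction`
#'   pointing into the scene.
#' @export
back_project_ray <- function(P, uv) {
  M <- P[, 1:3]
  dir <- as.numeric(solve(M, c(uv, 1)))
  dir <- dir / sqrt(sum(dir^2))
  if (sum(dir * principal_direction(P)) < 0) dir <- -dir
  list(origin = camera_center(P), direction = dir)
}

# closest-approach midpoint of two (possibly skew) lines given as origin o, unit dir d
ray_midpoint <- function(o1, d1, o2, d2) {
  # solve [d1.d1 -d1.d2; d1.d2 -d2.d2] (s,t)' = ((o2-o1).d1, (o2-o1).d2)
  b <- o2 - o1
  d11 <- sum(d1 * d1); d12 <- sum(d1 * d2); d22 <- sum(d2 * d2)
  den <- d11 * d22 - d12^2
  if (abs(den) < 1e-12) stop("rays are parallel; cannot triangulate")
  s <- (sum(b * d1) * d22 - sum(b * d2) * d12) / den
  t <- (sum(b * d1) * d12 - sum(b * d2) * d11) / den
  (o1 + s * d1 + o2 + t * d2) / 2
}

#' Rigid transform (3-DOF translation)
#'
#' The registration state. Rotation is fixed to the identity: reference
#' registrations of the left atrium are translation-only (patient positioning
#' rules out large rotations and small ones are not reliably observable from
#' sparse contrast), so the whole pipeline estimates a 3-vector in mm.
#'
#' @param t Length-3 numeric translation (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(t = c(0, 0, 0)) {
  t <- as.numeric(t)
  if (length(t) != 3L || !all(is.finite(t)))
    stop("translation must be a finite length-3 numeric")
  structure(list(t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.3f, %.3f, %.3f) mm\n", x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

as_translation <- function(T) {
  if (inherits(T, "rigid_transform")) T$t else {
    t <- as.numeric(T)
    if (length(t) != 3L) stop("expected a rigid_transform or length-3 translation")
    t
  }
}

#' Initialization at the image centres
#'
#' Back-projects the centre pixel of each plane and returns the midpoint of the
#' closest-approach segment of the two centre rays: the 3D position that
#' appears at the centre of both images. Used as the default starting point of
#' the translation search.
#'
#' @param geometry A [projection_geometry()].
#' @return A [rigid_transform()].
#' @export
initialize_translation <- function(geometry) {
  stopifnot(inherits(geometry, "projection_geometry"))
  ctr <- (rev(geometry$image_shape) - 1) / 2   # (u, v) of the image centre
  rA <- back_project_ray(geometry$P_A, ctr)
  rB <- back_project_ray(geometry$P_B, ctr)
  rigid_transform(ray_midpoint(rA$origin, rA$direction, rB$origin, rB$direction))
}
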