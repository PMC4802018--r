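# Projective geometry and the three renderers.

test_that("project_point implements the pinhole model", {
  P <- cbind(diag(3), c(0, 0, 0))
  expect_equal(project_point(P, c(2, 3, 4)), c(2 / 4, 3 / 4))
  # moving along the principal ray leaves the pixel unchanged
  expect_equal(project_point(P, c(2, 3, 8)), c(0.25, 0.375))
  expect_equal(project_point(P, 2 * c(1, 1, 5)), project_point(P, c(1, 1, 5)))
  expect_error(project_point(P, c(1, 1, 0)), "infinity")
})

test_that("pixel -> ray -> pixel round-trips to 1e-9", {
  g <- fx_geometry(128L)
  set.seed(2)
  for (i in 1:20) {
    uv <- runif(2, 5, 120)
    r <- back_project_ray(g$P_A, uv)
    for (lam in c(300, 750, 1100)) {
      p <- r$origin + lam * r$direction
      expect_equal(project_point(g$P_A, p), uv, tolerance = 1e-9)
    }
  }
})

test_that("image-center initialization triangulates the iso-center", {
  g <- fx_geometry(128L)
  init <- initialize_translation(g)
  expect_equal(init$t, c(0, 0, 0), tolerance = 1e-6)
  # skew rays: midpoint is equidistant from both rays
  g2 <- make_biplane_geometry(c(64L, 64L), angle_A = 10, angle_B = 75)
  ctr <- (rev(g2$image_shape) - 1) / 2
  rA <- back_project_ray(g2$P_A, ctr + c(3, 0))
  rB <- back_project_ray(g2$P_B, ctr - c(0, 2))
  q <- atriareg:::ray_midpoint(rA$origin, rA$direction, rB$origin, rB$direction)
  dist_to_ray <- function(q, r) {
    v <- q - r$origin
    sqrt(sum((v - sum(v * r$direction) * r$direction)^2))
  }
  expect_equal(dist_to_ray(q, rA), dist_to_ray(q, rB), tolerance = 1e-9)
  # parallel principal rays are rejected at construction
  expect_error(make_biplane_geometry(c(64, 64), angle_A = 0, angle_B = 180),
               "parallel")
})

test_that("shadow of a sphere matches pinhole magnification", {
  spec <- phantom_spec(body_radii = c(20, 20, 20), pv_specs = list(),
                       voxel_spacing = 1, grid_shape = c(48L, 48L, 48L))
  m <- build_phantom(spec)
  g <- make_biplane_geometry(c(256L, 256L))
  S <- render_shadow(m, g$P_A, c(0, 0, 0), g$image_shape)
  # analytic: radius * SID/SOD / pixel_spacing at the iso-center
  ps <- g$pixel_spacing
  r_expect <- 20 * 1200 / 750 / ps
  r_measured <- sqrt(sum(S) / pi)
  expect_lt(abs(r_measured - r_expect), 2)

  # empty model renders an all-zero image
  empty <- m; empty$volume[] <- FALSE
  expect_true(all(render_shadow(empty, g$P_A, c(0, 0, 0), g$image_shape) == 0))

  # shadow area shrinks as the model recedes from the source (y axis for plane A)
  areas <- vapply(c(-60, 0, 60), function(dy)
    sum(render_shadow(m, g$P_A, c(0, dy, 0), g$image_shape)), numeric(1))
  expect_true(all(diff(areas) < 0))
})

cross3_t <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])

test_that("apparent-edge opacity follows 1 - |d.n|", {
  expect_equal(triangle_opacity(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(triangle_opacity(c(0, 1, 0), c(1, 0, 0)), 1)
  d45 <- c(0, sqrt(2) / 2, sqrt(2) / 2)
  expect_equal(triangle_opacity(c(0, 1, 0), d45), 1 - sqrt(2) / 2)

  # rendered single triangles: value at the centroid pixel equals the opacity
  g <- fx_geometry(128L)
  src <- g$source_A
  mk_tri <- function(n) {
    # small triangle at the iso-center whose normal is n
    b1 <- if (abs(n[1]) < 0.9) cross3_t(n, c(1, 0, 0)) else cross3_t(n, c(0, 1, 0))
    b1 <- b1 / sqrt(sum(b1^2)); b2 <- cross3_t(n, b1)
    V <- rbind(2 * b1, -b1 + 1.5 * b2, -b1 - 1.5 * b2)
    triangle_mesh(V, matrix(1:3, 1), normals = matrix(n, 1))
  }
  d <- c(0, 0, 0) - src; d <- d / sqrt(sum(d^2))   # viewing direction at iso-center
  for (ang in c(0, 45, 90)) {
    # rotate the normal by `ang` degrees away from d, about the z axis
    th <- ang * pi / 180
    n <- c(sin(th) * 1, cos(th) * d[2], 0); n <- n / sqrt(sum(n^2))
    mesh <- mk_tri(n)
    E <- render_apparent_edges(mesh, g$P_A, c(0, 0, 0), g$image_shape)
    uv <- project_point(g$P_A, c(0, 0, 0))
    got <- max(E)
    expect_equal(got, 1 - abs(sum(d * n)), tolerance = 1e-6)
    expect_gte(min(E), 0)
  }
})

test_that("compute_cade equals the brute-force triple-condition oracle", {
  m <- fx_toy16()
  g <- fx_toy_geometry()
  set.seed(9)
  shp <- g$image_shape
  # hand-placed binary masks: random rectangles plus scattered pixels
  mk_mask <- function() {
    M <- matrix(0, shp[1], shp[2])
    for (k in 1:3) {
      r0 <- sample(1:48, 1); c0 <- sample(1:48, 1)
      M[r0:(r0 + sample(4:14, 1)), c0:(c0 + sample(4:14, 1))] <- 1
    }
    M[sample(length(M), 40)] <- 1
    M
  }
  IA <- mk_mask(); IB <- mk_mask()
  for (trial in 1:10) {
    t <- runif(3, -12, 12)
    got <- compute_cade(m, IA, IB, g, t)
    want <- brute_force_cade(m, IA, IB, g, t)
    expect_identical(got$C3D, want)
  }
})

test_that("CADE honours its trivial limits and containment invariants", {
  m <- fx_toy16()
  g <- fx_toy_geometry()
  shp <- g$image_shape
  ones <- matrix(1, shp[1], shp[2]); zeros <- matrix(0, shp[1], shp[2])
  # chi = 0 everywhere -> empty estimate
  empty <- m; empty$volume[] <- FALSE
  r0 <- compute_cade(empty, ones, ones, g, c(0, 0, 0))
  expect_true(all(!r0$C3D) && all(r0$C_A == 0))
  # both masks full -> whole chamber contrasted
  r1 <- compute_cade(m, ones, ones, g, c(0, 0, 0))
  expect_identical(r1$C3D, m$volume)
  # containment: C3D subset of chi always
  rr <- compute_cade(m, ones, zeros, g, c(0, 0, 0))
  expect_true(all(!rr$C3D))
  # shadow is the CADE upper bound: support of C_A under full masks == shadow
  S <- render_shadow(m, g$P_A, c(0, 0, 0), shp)
  expect_identical(r1$C_A, S)
})

test_that("renderers shift consistently with the projected translation", {
  m <- fx_toy16()
  g <- fx_toy_geometry()
  # a pure cranio-caudal shift by one projected pixel moves the shadow by
  # one row (v grows caudally, -z): compare shifted supports
  ps <- g$pixel_spacing
  mm_per_px <- ps * 750 / 1200         # at iso-center depth
  S0 <- render_shadow(m, g$P_A, c(0, 0, 0), g$image_shape)
  S1 <- render_shadow(m, g$P_A, c(0, 0, -3 * mm_per_px), g$image_shape)
  shifted <- rbind(matrix(0, 3, ncol(S0)), S0[1:(nrow(S0) - 3), ])
  agree <- mean(shifted == S1)
  expect_gt(agree, 0.995)
})
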