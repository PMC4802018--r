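# Scalar similarity measures and their algebraic structure.

test_that("ncc matches the direct double-sum definition on random pairs", {
  set.seed(100)
  for (i in 1:100) {
    I1 <- matrix(rnorm(64), 8, 8)
    I2 <- matrix(rnorm(64), 8, 8)
    expect_lt(abs(ncc(I1, I2) - ncc_direct(I1, I2)), 1e-10)
  }
})

test_that("ncc is affine-invariant, bounded and handles zero variance", {
  set.seed(1)
  I <- matrix(runif(100), 10, 10)
  expect_equal(ncc(I, I), 1)
  expect_equal(ncc(I, 3 * I + 7), 1)
  expect_equal(ncc(I, -2 * I + 1), -1)
  expect_identical(ncc(I, matrix(5, 10, 10)), 0)   # constant -> no information
  expect_identical(ncc(matrix(0, 10, 10), I), 0)
  expect_error(ncc(I, matrix(0, 5, 5)), "shape")
  for (k in 1:20) {
    v <- ncc(matrix(rnorm(64), 8), matrix(rnorm(64), 8))
    expect_true(v >= -1 && v <= 1)
  }
})

test_that("similarity measures carry the two-plane product structure", {
  m <- fx_toy16()
  g <- fx_toy_geometry()
  shp <- g$image_shape
  S_A <- render_shadow(m, g$P_A, c(0, 0, 0), shp)
  S_B <- render_shadow(m, g$P_B, c(0, 0, 0), shp)
  # plane B perfectly matched, plane A anti-matched -> negative product
  prepA <- list(I_thr = 1 - S_A, I_DSA = 1 - S_A, I_DOG = matrix(0, shp[1], shp[2]))
  prepB <- list(I_thr = S_B, I_DSA = S_B, I_DOG = matrix(0, shp[1], shp[2]))
  v <- rho_shadow(prepA, prepB, m, g, c(0, 0, 0), variant = "thr")
  expect_lt(v, 0)
  expect_equal(abs(v), 1, tolerance = 1e-12)
  # model fully outside both images -> sigma = 0 convention gives 0
  far <- rho_shadow(prepA, prepB, m, g, c(5000, 0, 0), variant = "thr")
  expect_identical(far, 0)
})

test_that("edge measure is zero for an empty mesh and peaks near truth", {
  sim <- fx_clean_full_sim()
  m <- fx_model(); g <- fx_geometry(128L)
  prepA <- preprocess_plane(sim$sequence, 3, "A")
  prepB <- preprocess_plane(sim$sequence, 3, "B")
  empty <- m
  empty$mesh <- triangle_mesh(matrix(0, 3, 3), matrix(1:3, 1))  # degenerate only
  expect_identical(rho_edge(prepA, prepB, empty, g, c(0, 0, 0)), 0)

  ctx <- atriareg:::make_eval_context(m, g, prepA, prepB)
  tt <- sim$truth$translations[3, ]
  v0 <- rho_edge(NULL, NULL, NULL, NULL, tt, ctx = ctx)
  for (off in list(c(10, 0, 0), c(-10, 0, 0), c(0, 0, 10), c(0, 0, -10)))
    expect_gt(v0, rho_edge(NULL, NULL, NULL, NULL, tt + off, ctx = ctx))
})

test_that("combined measure is linear in alpha and reduces to the base", {
  sim <- fx_clean_full_sim()
  m <- fx_model(); g <- fx_geometry(128L)
  prepA <- preprocess_plane(sim$sequence, 3, "A")
  prepB <- preprocess_plane(sim$sequence, 3, "B")
  ctx <- atriareg:::make_eval_context(m, g, prepA, prepB)
  t0 <- c(3, -2, 5)
  base <- rho_combined(NULL, NULL, NULL, NULL, t0, similarity_config("shad_thr"), ctx = ctx)
  edge <- rho_combined(NULL, NULL, NULL, NULL, t0, similarity_config("edge"), ctx = ctx)
  for (a in c(0.5, 1, 2)) {
    comb <- rho_combined(NULL, NULL, NULL, NULL, t0,
                         similarity_config("shad_thr+edge", alpha = a), ctx = ctx)
    expect_equal(comb - base, a * edge, tolerance = 1e-10)
  }
  expect_error(similarity_config("shad_thr", alpha = 0), "alpha")
})

test_that("shad_thr and cade peak at the true pose of a clean full phantom", {
  sim <- fx_clean_full_sim()
  m <- fx_model(); g <- fx_geometry(128L)
  prepA <- preprocess_plane(sim$sequence, 3, "A")
  prepB <- preprocess_plane(sim$sequence, 3, "B")
  ctx <- atriareg:::make_eval_context(m, g, prepA, prepB)
  tt <- sim$truth$translations[3, ]
  # argmax over a 2 mm lattice lies within one lattice step of the truth
  offs <- expand.grid(x = seq(-8, 8, 2), y = seq(-8, 8, 2), z = seq(-8, 8, 2))
  for (meas in c("shad_thr", "cade")) {
    cfgm <- similarity_config(meas)
    vals <- apply(offs, 1, function(o)
      rho_combined(NULL, NULL, NULL, NULL, tt + as.numeric(o), cfgm, ctx = ctx))
    best <- as.numeric(offs[which.max(vals), ])
    expect_lte(max(abs(best)), 2)
  }
  # with exact footprint masks, splat discretization is the only loss and the
  # CADE consistency at truth is near-perfect
  S_A <- render_shadow(m, g$P_A, tt, g$image_shape)
  S_B <- render_shadow(m, g$P_B, tt, g$image_shape)
  zero <- matrix(0, g$image_shape[1], g$image_shape[2])
  exact <- atriareg:::make_eval_context(m, g,
    list(I_thr = S_A, I_DSA = S_A, I_DOG = zero),
    list(I_thr = S_B, I_DSA = S_B, I_DOG = zero))
  expect_gte(rho_cade(NULL, NULL, NULL, NULL, tt, ctx = exact), 0.95)
  # through the full preprocessing (median-threshold erosion included) the
  # value stays high
  expect_gte(rho_cade(NULL, NULL, NULL, NULL, tt, ctx = ctx), 0.9)
})

test_that("cade rejects the count-maximizing biased pose on a vein injection", {
  sim <- fx_vein_sim(128L)
  m <- fx_model(); g <- fx_geometry(128L)
  fr <- max(which(sim$sequence$contrasted))
  prepA <- preprocess_plane(sim$sequence, fr, "A")
  prepB <- preprocess_plane(sim$sequence, fr, "B")
  tt <- sim$truth$translations[fr, ]
  # biased pose: slide the chamber along the injected vein so the vein's
  # contrast falls into the large chamber body
  vein_dir <- m$pv_tips[[1]] / sqrt(sum(m$pv_tips[[1]]^2))
  biased <- tt + 20 * vein_dir
  cade_true <- compute_cade(m, prepA$I_thr, prepB$I_thr, g, tt)
  cade_bias <- compute_cade(m, prepA$I_thr, prepB$I_thr, g, biased)
  expect_gt(sum(cade_bias$C3D), sum(cade_true$C3D))   # count prefers the bias...
  ctx <- atriareg:::make_eval_context(m, g, prepA, prepB)
  v_true <- rho_cade(NULL, NULL, NULL, NULL, tt, ctx = ctx)
  v_bias <- rho_cade(NULL, NULL, NULL, NULL, biased, ctx = ctx)
  expect_gt(v_true, v_bias)                            # ...consistency does not
})
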