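# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_get <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# standard phantom model (ellipsoid + 4 veins, 2 mm voxels)
fx_model <- function(seed = 1L) {
  fx_get(sprintf("model_%d", seed), function() build_phantom(phantom_spec(seed = seed)))
}

fx_geometry <- function(size = 128L) {
  fx_get(sprintf("geom_%d", size), function() make_biplane_geometry(c(size, size)))
}

# noiseless, artifact-free, fully-filled two-frame sequence (frame 1
# uncontrasted reference, frame 2 fully opacified), no breathing
fx_clean_full_sim <- function(size = 128L, seed = 2L) {
  fx_get(sprintf("cleanfull_%d_%d", size, seed), function() {
    sc <- injection_scenario(fill_fractions = c(0, 0, 1), breathing_amplitude = 0,
                             artifact_flags = list(catheter = FALSE, diaphragm = FALSE),
                             noise_sd = 0)
    simulate_sequence(fx_model(), sc, fx_geometry(size), seed = seed)
  })
}

# realistic center-injection sequence with artifacts and noise
fx_center_sim <- function(size = 128L, seed = 5L) {
  fx_get(sprintf("center_%d_%d", size, seed), function()
    simulate_sequence(fx_model(), scenario_center_injection(), fx_geometry(size),
                      seed = seed))
}

# partial vein-injection sequence
fx_vein_sim <- function(size = 128L, seed = 3L) {
  fx_get(sprintf("vein_%d_%d", size, seed), function()
    simulate_sequence(fx_model(), scenario_vein_injection(vein = 1L),
                      fx_geometry(size), seed = seed))
}

# tiny 16^3 toy model for brute-force CADE comparisons: an off-centre blob
fx_toy16 <- function() {
  fx_get("toy16", function() {
    spec <- phantom_spec(body_radii = c(9, 7, 8), pv_specs = list(),
                         voxel_spacing = 2, grid_shape = c(16L, 16L, 16L))
    build_phantom(spec)
  })
}

# small-geometry helper for toy tests
fx_toy_geometry <- function() fx_get("toygeom", function() make_biplane_geometry(c(64L, 64L)))

# brute-force CADE oracle: per-voxel evaluation of the three conditions with
# scalar projections (independent of the vectorized implementation)
brute_force_cade <- function(model, I_thr_A, I_thr_B, geometry, t) {
  d <- dim(model$volume)
  C <- array(FALSE, d)
  look <- function(P, p) {
    uv <- project_point(P, p)
    u <- round(uv[1]); v <- round(uv[2])
    I <- if (identical(P, geometry$P_A)) I_thr_A else I_thr_B
    if (u < 0 || u >= ncol(I) || v < 0 || v >= nrow(I)) return(FALSE)
    I[v + 1, u + 1] > 0
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!model$volume[i, j, k]) next
    p <- model$origin + (c(i, j, k) - 1) * model$spacing + t
    C[i, j, k] <- look(geometry$P_A, p) && look(geometry$P_B, p)
  }
  C
}

# direct double-sum normalized cross-correlation (population statistics)
ncc_direct <- function(I1, I2) {
  m1 <- mean(I1); m2 <- mean(I2)
  s1 <- sqrt(mean((I1 - m1)^2)); s2 <- sqrt(mean((I2 - m2)^2))
  acc <- 0
  for (x in seq_len(nrow(I1))) for (y in seq_len(ncol(I1)))
    acc <- acc + (I1[x, y] - m1) * (I2[x, y] - m2)
  acc / (length(I1) * s1 * s2)
}

# synthetic 10-frame single-plane stack with a moving catheter artifact,
# for reference-selection tests
make_catheter_stack <- function(seed, shp = c(64L, 64L), n = 10L) {
  set.seed(seed)
  rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
  cc <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
  lapply(seq_len(n), function(i) {
    xc <- shp[2] * runif(1, 0.2, 0.8) + 3 * sin(0.4 * rr)
    2000 - 400 * exp(-(cc - xc)^2 / 8) + matrix(rnorm(prod(shp), 0, 5), shp[1])
  })
}

# family of phantoms with varied anatomy (body size, vein orientation and
# calibre differ per seed), mirroring the way clinical evaluations average
# over patients rather than repeating one anatomy
fx_family_spec <- function(seed) {
  set.seed(seed)
  radii <- c(28, 22, 25) * runif(3, 0.85, 1.15)
  dirs <- list(c(-0.75, 0.45, 0.5), c(0.75, 0.45, 0.5),
               c(-0.75, 0.45, -0.5), c(0.75, 0.45, -0.5))
  pv <- lapply(dirs, function(d) list(direction = d + runif(3, -0.15, 0.15),
                                      radius = runif(1, 4.5, 6),
                                      length = runif(1, 18, 24)))
  phantom_spec(body_radii = radii, pv_specs = pv, seed = seed)
}
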