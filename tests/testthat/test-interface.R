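# File round-trips, validation errors and the end-to-end pipeline.

test_that("geometry JSON round-trips exactly", {
  g <- fx_geometry(128L)
  path <- tempfile(fileext = ".json")
  write_geometry(g, path)
  g2 <- read_geometry(path)
  expect_equal(g2$P_A, g$P_A)
  expect_equal(g2$P_B, g$P_B)
  expect_identical(g2$image_shape, g$image_shape)
  expect_error(read_geometry(tempfile()), "no such file")
})

test_that("model files round-trip: volume <-> mesh stay consistent", {
  m <- fx_toy16()
  prefix <- tempfile()
  write_model(m, prefix)
  # volume path: indicator and spacing survive, surface is re-extracted closed
  m2 <- read_model(paste0(prefix, ".nii.gz"))
  expect_identical(m2$volume, m$volume)
  expect_equal(m2$spacing, m$spacing)
  expect_true(is_watertight(m2$mesh))
  # mesh path: voxelizing the written STL reproduces the volume within 5%
  m3 <- read_model(paste0(prefix, ".stl"), spacing = m$spacing)
  v_orig <- sum(m$volume) * m$spacing^3
  v_back <- sum(m3$volume) * m3$spacing^3
  expect_lt(abs(v_back - v_orig) / v_orig, 0.05)
  expect_error(read_model(tempfile(fileext = ".stl")), "no such file")
})

test_that("voxelization of an analytic cube matches its volume and rejects open meshes", {
  # 10 mm cube, vertices at +-5: 12 triangles
  v <- as.matrix(expand.grid(x = c(-5, 5), y = c(-5, 5), z = c(-5, 5)))
  faces <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),   # z faces
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),   # y faces
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))   # x faces
  cube <- triangle_mesh(v, faces)
  expect_true(is_watertight(cube))
  A <- atriareg:::voxelize_mesh(cube, 1, c(14L, 14L, 14L), c(-6.5, -6.5, -6.5))
  # 1000 mm^3 within a one-voxel boundary shell (6 faces of ~100 voxels)
  expect_lt(abs(sum(A) - 1000), 6 * 100 * 0.5 + 1)
  open_mesh <- triangle_mesh(v, faces[-1, , drop = FALSE])
  expect_error(atriareg:::voxelize_mesh(open_mesh, 1, c(14L, 14L, 14L),
                                        c(-6.5, -6.5, -6.5)), "watertight")
})

test_that("sequences round-trip losslessly through TIFF + sidecar", {
  sim <- fx_center_sim(64L)
  dir <- tempfile()
  write_sequence(sim$sequence, dir, truth = sim$truth)
  s2 <- read_sequence(dir)
  expect_equal(s2$frames_A, sim$sequence$frames_A)
  expect_equal(s2$frames_B, sim$sequence$frames_B)
  expect_identical(s2$contrasted, sim$sequence$contrasted)
  expect_equal(s2$frame_rate, sim$sequence$frame_rate)
  expect_equal(attr(s2, "truth_translations"), sim$truth$translations)
  # validation: mismatched frame counts and missing annotations are named
  side <- jsonlite::read_json(file.path(dir, "sequence.json"), simplifyVector = TRUE)
  side$contrasted <- side$contrasted[-1]
  jsonlite::write_json(side, file.path(dir, "sequence.json"), auto_unbox = TRUE)
  expect_error(read_sequence(dir), "annotation")
  expect_error(read_sequence(tempfile()), "sidecar")
})

test_that("the pipeline produces a reproducible report with errors vs truth", {
  sim <- fx_center_sim(64L)
  m <- fx_model()
  cfg <- run_config(measure = "shad_thr", seed = 3,
                    search = search_config(range_mm = 16, level0_step_mm = 8,
                                           keep_top_k = 4, min_step_mm = 2))
  out1 <- tempfile(fileext = ".json"); out2 <- tempfile(fileext = ".json")
  rep1 <- run_pipeline(sim$sequence, m, cfg, truth = sim$truth, out = out1)
  rep2 <- run_pipeline(sim$sequence, m, cfg, truth = sim$truth, out = out2)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  expect_true(all(c("version", "seed", "config_hash", "frames", "best_frame",
                    "filtered", "log_counters") %in% names(rep1)))
  expect_true(all(rep1$frames$frame %in% which(sim$sequence$contrasted)))
  expect_true(all(is.finite(rep1$frames$error_mm)))
  expect_equal(nrow(rep1$filtered), nrow(rep1$frames))
})

test_that("trajectory objects tidy, glance and plot", {
  regs <- tibble::tibble(frame = 1:5, tx = rnorm(5), ty = rnorm(5), tz = rnorm(5),
                         rho = runif(5), measure = "cade", n_eval = 10L)
  class(regs) <- c("frame_registrations", class(regs))
  tr <- la_trajectory(regs, frame_rate = 7.5)
  conf <- structure(list(slope = 0, intercept = 2, floor = 0.1),
                    class = "confidence_model")
  trans <- structure(list(Sigma_v = diag(3), n_velocities = 5),
                     class = "transition_model")
  tr <- smooth_trajectory(tr, conf, trans)
  td <- tidy(tr)
  expect_true(all(c("tx_filtered", "ty_filtered", "tz_filtered") %in% names(td)))
  gl <- glance(tr)
  expect_identical(gl$n_frames, 5L)
  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(regs), "ggplot")
  ct <- tidy(conf)
  expect_identical(ct$term, c("(Intercept)", "rho"))
})

test_that("a YAML run configuration round-trips into run_config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("measure: shad_thr", "alpha: 0.5", "seed: 7",
               "search:", "  range_mm: 24", "  level0_step_mm: 8"), path)
  cfg <- read_run_config(path)
  expect_identical(cfg$measure, "shad_thr")
  expect_identical(cfg$seed, 7L)
  expect_equal(cfg$search$range_mm, 24)
  expect_error(read_run_config(tempfile()), "no such file")
})
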