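# Confidence regression, velocity covariance and Markov MAP smoothing.

mk_reg <- function(Tp, rho) {
  out <- tibble::tibble(frame = seq_len(nrow(Tp)), tx = Tp[, 1], ty = Tp[, 2],
                        tz = Tp[, 3], rho = rho)
  out
}
unit_conf <- structure(list(slope = 0, intercept = 1, floor = 0.1),
                       class = "confidence_model")
unit_trans <- structure(list(Sigma_v = diag(3), n_velocities = 10),
                        class = "transition_model")

test_that("confidence regression recovers exact and noisy linear relations", {
  rho <- seq(0, 1, length.out = 10)
  err <- 8 - 5 * rho
  cm <- fit_confidence(data.frame(rho = rho, error_mm = err))
  expect_equal(cm$slope, -5, tolerance = 1e-10)
  expect_equal(cm$intercept, 8, tolerance = 1e-10)
  # constant errors: slope 0, intercept the mean
  cm2 <- fit_confidence(data.frame(rho = rho, error_mm = rep(4.2, 10)))
  expect_equal(cm2$slope, 0, tolerance = 1e-10)
  expect_equal(cm2$intercept, 4.2, tolerance = 1e-10)
  # noisy fit matches the closed-form normal equations
  set.seed(31)
  rho <- runif(100); err <- pmax(6 - 4 * rho + rnorm(100, 0, 1), 0.1)
  cm3 <- fit_confidence(data.frame(rho = rho, error_mm = err))
  X <- cbind(1, rho)
  beta <- solve(t(X) %*% X, t(X) %*% err)
  expect_equal(c(cm3$intercept, cm3$slope), as.numeric(beta), tolerance = 1e-10)
  # degenerate input
  expect_error(fit_confidence(data.frame(rho = rep(0.5, 5), error_mm = 1:5)),
               "distinct rho")
  # predictions are clamped to the floor
  expect_gte(min(predict_error(cm, c(10, -10))), cm$floor)
})

test_that("velocity covariance obeys its analytic and scaling laws", {
  # constant trajectory: singular covariance -> error unless regularized
  const <- list(list(translations = matrix(1, 10, 3), frame_rate = 5))
  expect_error(fit_transition(const, regularize = FALSE), "regulari")
  tm0 <- fit_transition(const)          # default adds lambda * I
  expect_true(all(eigen(tm0$Sigma_v)$values > 0))

  # sinusoidal single-axis motion: variance concentrated on that axis and
  # matching the analytic covariance of the sampled derivative
  n <- 200; A <- 4; p <- 20; r <- 7.5
  z <- A * sin(2 * pi * (seq_len(n) - 1) / p)
  tm <- fit_transition(list(list(translations = cbind(0, 0, z), frame_rate = r)))
  lam <- 1e-6       # ridge added because single-axis motion is rank-1
  off_diag <- tm$Sigma_v[upper.tri(tm$Sigma_v)]
  expect_lt(max(abs(off_diag)), 1e-12)
  expect_equal(tm$Sigma_v[1, 1], lam, tolerance = 1e-9)
  dz <- diff(z) * r
  expect_equal(tm$Sigma_v[3, 3] - lam, mean(dz^2), tolerance = 1e-9)
  # doubling the frame rate quadruples the covariance
  tm2 <- fit_transition(list(list(translations = cbind(0, 0, z), frame_rate = 2 * r)))
  expect_equal(tm2$Sigma_v[3, 3] - lam, 4 * (tm$Sigma_v[3, 3] - lam),
               tolerance = 1e-9)

  expect_error(fit_transition(list(list(translations = matrix(0, 1, 3),
                                        frame_rate = 1))), ">= 2 frames")
})

test_that("smoothing solves the analytic scalar case and the trivial limits", {
  # scalar two-frame case: unit variances, estimates (0, 2) -> (2/3, 4/3)
  tr <- smooth_trajectory(mk_reg(rbind(c(0, 0, 0), c(2, 0, 0)), c(0.5, 0.5)),
                          unit_conf, unit_trans, frame_rate = 1)
  expect_equal(tr$filtered[, 1], c(2 / 3, 4 / 3), tolerance = 1e-8)
  # n = 1: no transition term, identity
  tr1 <- smooth_trajectory(mk_reg(matrix(c(5, -1, 2), 1), 0.7),
                           unit_conf, unit_trans, frame_rate = 1)
  expect_identical(tr1$filtered, matrix(c(5, -1, 2), 1))
  # infinite transition variance decouples the frames
  loose <- structure(list(Sigma_v = diag(3) * 1e12, n_velocities = 10),
                     class = "transition_model")
  Tp <- matrix(rnorm(15), 5, 3)
  trL <- smooth_trajectory(mk_reg(Tp, rep(0.5, 5)), unit_conf, loose, frame_rate = 7.5)
  expect_equal(trL$filtered, Tp, tolerance = 1e-6)
  # vanishing transition variance collapses to the confidence-weighted mean
  tight <- structure(list(Sigma_v = diag(3) * 1e-12, n_velocities = 10),
                     class = "transition_model")
  conf_w <- structure(list(slope = -2, intercept = 3, floor = 0.5),
                      class = "confidence_model")
  rho <- c(0.1, 0.9, 0.5)
  trT <- smooth_trajectory(mk_reg(Tp[1:3, ], rho), conf_w, tight, frame_rate = 1)
  w <- 1 / predict_error(conf_w, rho)^2
  wmean <- colSums(Tp[1:3, ] * w) / sum(w)
  for (i in 1:3) expect_equal(trT$filtered[i, ], wmean, tolerance = 1e-4)
  # non-PD covariance is refused
  bad <- structure(list(Sigma_v = matrix(0, 3, 3), n_velocities = 1),
                   class = "transition_model")
  expect_error(smooth_trajectory(mk_reg(Tp, rep(0.5, 5)), unit_conf, bad, 1),
               "positive-definite")
})

test_that("BFGS smoothing matches the block-tridiagonal solve on random problems", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    Tp <- matrix(rnorm(3 * n, 0, 5), n, 3)
    reg <- mk_reg(Tp, runif(n))
    S <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.5
    trans <- structure(list(Sigma_v = S, n_velocities = 10),
                       class = "transition_model")
    conf <- structure(list(slope = -2, intercept = 3, floor = 0.5),
                      class = "confidence_model")
    a <- smooth_trajectory(reg, conf, trans, frame_rate = 7.5)$filtered
    b <- smooth_trajectory_exact(reg, conf, trans, frame_rate = 7.5)
    expect_lt(max(abs(a - b)), 1e-8)
  }
})

test_that("an outlier frame is pulled towards its accurate neighbours", {
  truth <- matrix(0, 7, 3)
  Tp <- truth; Tp[4, ] <- c(12, -9, 6)      # single gross outlier
  rho <- rep(0.9, 7); rho[4] <- 0.1         # and the measure knows it
  conf <- structure(list(slope = -10, intercept = 10.5, floor = 0.5),
                    class = "confidence_model")
  trans <- structure(list(Sigma_v = diag(3) * 4, n_velocities = 50),
                     class = "transition_model")
  tr <- smooth_trajectory(mk_reg(Tp, rho), conf, trans, frame_rate = 1)
  ev_raw <- evaluate_trajectory(Tp, truth)
  ev_fil <- evaluate_trajectory(tr$filtered, truth)
  expect_lt(ev_fil$error_mm[4], ev_raw$error_mm[4])
  expect_lt(attr(ev_fil, "mean_error"), attr(ev_raw, "mean_error"))
  # exact-equality and averaging contracts of the evaluator
  ev0 <- evaluate_trajectory(truth, truth)
  expect_true(all(ev0$error_mm == 0))
  expect_equal(attr(ev_raw, "mean_error"), mean(ev_raw$error_mm))
})

test_that("leave-one-sequence-out filtering never trains on the held-out run", {
  set.seed(55)
  runs <- lapply(1:4, function(k) {
    n <- 12
    z <- 4 * sin(2 * pi * (seq_len(n) - 1) / 8)
    truth <- structure(list(translations = cbind(0, 0, z)), class = "ground_truth")
    noise <- matrix(rt(3 * n, df = 2), n, 3) * 1.5
    Tp <- truth$translations + noise
    err <- sqrt(rowSums(noise^2))
    regs <- mk_reg(Tp, pmax(pmin(1 - err / 20, 1), 0) + rnorm(n, 0, 0.02))
    regs$error_mm <- err
    list(registrations = regs, truth = truth, frame_rate = 7.5)
  })
  filtered <- crossval_filter(runs)
  expect_length(filtered, 4)
  # the training data for run k excludes run k: poisoning run 1's own rows
  # must not change its filtered output
  runs_poisoned <- runs
  runs_poisoned[[1]]$registrations$error_mm <- runs[[1]]$registrations$error_mm * 100
  f2 <- crossval_filter(runs_poisoned)
  expect_identical(filtered[[1]]$filtered, f2[[1]]$filtered)
  expect_false(identical(filtered[[2]]$filtered, f2[[2]]$filtered))
})
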