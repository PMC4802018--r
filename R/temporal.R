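# Confidence-weighted Markov-chain smoothing of per-frame translations.
# The per-frame state probability is an isotropic Gaussian around the
# unfiltered estimate whose scale comes from a linear regression of observed
# error on similarity value; the transition probability is a zero-mean
# Gaussian on the inter-frame velocity with covariance learned from
# annotated trajectories. The MAP sequence maximizes the product of state
# and transition probabilities, equivalently minimizes a convex quadratic.

#' Fit the confidence regression e(rho)
#'
#' Ordinary least squares of the observed registration error (mm) on the
#' similarity value. Higher similarity predicts lower error; the prediction
#' is clamped below by a positive floor so state covariances stay
#' positive-definite.
#'
#' @param training Data frame (or tibble) with columns `rho` and `error_mm`,
#'   one row per registered training frame.
#' @return Object of class `confidence_model` with `slope`, `intercept` and
#'   `floor` (mm).
#' @export
fit_confidence <- function(training) {
  training <- as.data.frame(training)
  stopifnot(all(c("rho", "error_mm") %in% names(training)))
  if (nrow(training) < 2 || length(unique(training$rho)) < 2)
    stop("need at least 2 distinct rho values to fit the confidence regression")
  fit <- stats::lm(error_mm ~ rho, data = training)
  fitted_vals <- stats::fitted(fit)
  pos <- fitted_vals[fitted_vals > 0]
  floor_mm <- max(0.1, if (length(pos)) min(pos) else 0.1)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 floor = floor_mm),
            class = "confidence_model")
}

#' Predicted error for a similarity value
#'
#' @param object A `confidence_model`.
#' @param rho Similarity value(s).
#' @return Predicted error in mm, clamped to the model floor.
#' @export
predict_error <- function(object, rho) {
  pmax(object$intercept + object$slope * rho, object$floor)
}

#' @export
print.confidence_model <- function(x, ...) {
  cat(sprintf("<confidence_model> e(rho) = %.3f %+.3f * rho (floor %.2f mm)\n",
              x$intercept, x$slope, x$floor))
  invisible(x)
}

#' Fit the transition (velocity) covariance
#'
#' Velocities are successive translation differences scaled by the frame
#' rate. Because the chamber oscillates about a mean position over breathing
#' cycles, the mean transformation change is the identity: the covariance is
#' computed about zero, `Sigma_v = (1/n) sum v v^T`.
#'
#' @param trajectories List of trainings; each a list with `translations`
#'   (n x 3 matrix, mm) and `frame_rate` (frames/s), or a `ground_truth`
#'   plus `frame_rate`.
#' @param regularize Add `lambda * I` (`lambda` = 1e-6 (mm/s)^2) when the
#'   sample covariance is singular, e.g. for constant training motion. With
#'   `regularize = FALSE` a singular covariance is an error.
#' @return Object of class `transition_model` with `Sigma_v` (3x3, (mm/s)^2)
#'   and `n_velocities`.
#' @export
fit_transition <- function(trajectories, regularize = TRUE) {
  vel <- list()
  for (tr in trajectories) {
    X <- if (inherits(tr, "ground_truth")) tr$translations else tr$translations
    r <- tr$frame_rate
    if (is.null(X) || is.null(r)) stop("each trajectory needs translations and frame_rate")
    X <- as.matrix(X)
    if (nrow(X) >= 2) vel[[length(vel) + 1L]] <- diff(X) * r
  }
  if (!length(vel)) stop("need at least one trajectory with >= 2 frames")
  V <- do.call(rbind, vel)
  Sigma <- crossprod(V) / nrow(V)          # zero mean imposed
  if (rcond_psd(Sigma) < 1e-12) {
    if (!regularize)
      stop("velocity covariance is singular (constant training motion); ",
           "regularization required")
    la_log_bump("transition_regularized")
    Sigma <- Sigma + diag(1e-6, 3)
  }
  structure(list(Sigma_v = Sigma, n_velocities = nrow(V)),
            class = "transition_model")
}

rcond_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else max(min(ev), 0) / max(ev)
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> Sigma_v from %d velocities, diag = (%.2f, %.2f, %.2f) (mm/s)^2\n",
              x$n_velocities, x$Sigma_v[1, 1], x$Sigma_v[2, 2], x$Sigma_v[3, 3]))
  invisible(x)
}

#' Trajectory container
#'
#' @param registrations A `frame_registrations` tibble (unfiltered per-frame
#'   estimates with similarity values).
#' @param frame_rate Frames per second.
#' @return Object of class `la_trajectory`.
#' @export
la_trajectory <- function(registrations, frame_rate) {
  structure(list(registrations = registrations, frame_rate = frame_rate,
                 filtered = NULL, Sigma_diag = NULL),
            class = "la_trajectory")
}

#' Markov-chain MAP smoothing of a trajectory
#'
#' Minimizes
#' `sum_i (T_i - T_i')^T Sigma_i^{-1} (T_i - T_i') +
#'  sum_{i>=2} r^2 (T_i - T_{i-1})^T Sigma_v^{-1} (T_i - T_{i-1})`
#' over the stacked translations, where `Sigma_i = e(rho_i)^2 I` comes from
#' the confidence model and `Sigma_v` from the transition model. The problem
#' is a convex quadratic; it is solved by BFGS started at the unfiltered
#' estimates (the exact block-tridiagonal solve is kept as an independent
#' verification path, see [smooth_trajectory_exact()]).
#'
#' @param trajectory An `la_trajectory`, or a `frame_registrations` tibble
#'   plus `frame_rate`.
#' @param confidence A `confidence_model`.
#' @param transition A `transition_model`.
#' @param frame_rate Needed when `trajectory` is a bare tibble.
#' @return The trajectory with `$filtered` set to an n x 3 matrix of smoothed
#'   translations and `$Sigma_diag` to the per-frame state variances (mm^2).
#' @export
smooth_trajectory <- function(trajectory, confidence, transition, frame_rate = NULL) {
  tr <- as_la_trajectory(trajectory, frame_rate)
  reg <- tr$registrations
  n <- nrow(reg)
  if (n < 1) stop("empty trajectory")
  Tp <- unname(as.matrix(reg[, c("tx", "ty", "tz")]))
  e <- predict_error(confidence, reg$rho)
  sig2 <- e^2                              # isotropic variance, mm^2
  Sv_inv <- solve_pd(transition$Sigma_v)
  r2 <- tr$frame_rate^2
  objgrad <- markov_objective(Tp, sig2, Sv_inv, r2)
  if (n == 1) {
    tr$filtered <- Tp
  } else {
    x <- bfgs_minimize(as.vector(t(Tp)), objgrad$gr, objgrad$hvp)
    tr$filtered <- matrix(x, n, 3, byrow = TRUE)
  }
  tr$Sigma_diag <- sig2
  tr
}

as_la_trajectory <- function(trajectory, frame_rate) {
  if (inherits(trajectory, "la_trajectory")) return(trajectory)
  if (is.null(frame_rate)) stop("frame_rate required for a bare registration table")
  la_trajectory(trajectory, frame_rate)
}

solve_pd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance matrix is not positive-definite")
  solve(S)
}

# quadratic objective and gradient on the stacked state (x = t(T) flattened,
# frame-major). State term uses Sigma_i^{-1} = I / sig2_i.
markov_objective <- function(Tp, sig2, Sv_inv, r2) {
  n <- nrow(Tp)
  fn <- function(x) {
    X <- matrix(x, n, 3, byrow = TRUE)
    D <- X - Tp
    state <- sum(rowSums(D^2) / sig2)
    if (n > 1) {
      V <- diff(X)
      trans <- r2 * sum(V * (V %*% Sv_inv))
    } else trans <- 0
    state + trans
  }
  gr <- function(x) {
    X <- matrix(x, n, 3, byrow = TRUE)
    G <- 2 * (X - Tp) / sig2
    if (n > 1) {
      V <- diff(X) %*% Sv_inv              # (n-1) x 3
      G[-1, ] <- G[-1, ] + 2 * r2 * V
      G[-n, ] <- G[-n, ] - 2 * r2 * V
    }
    as.vector(t(G))
  }
  # Hessian-vector product (the objective is quadratic, so H is constant);
  # used for the exact line search inside BFGS, never to solve H x = b.
  hvp <- function(v) {
    Xv <- matrix(v, n, 3, byrow = TRUE)
    G <- 2 * Xv / sig2
    if (n > 1) {
      V <- diff(Xv) %*% Sv_inv
      G[-1, ] <- G[-1, ] + 2 * r2 * V
      G[-n, ] <- G[-n, ] - 2 * r2 * V
    }
    as.vector(t(G))
  }
  list(fn = fn, gr = gr, hvp = hvp)
}

# BFGS with exact line search for a convex quadratic: the step length along
# a descent direction d is alpha = -(g.d)/(d.Hd), available analytically via
# the Hessian-vector product. Inverse-Hessian approximation updated with the
# standard BFGS rank-two formula.
bfgs_minimize <- function(x0, gr, hvp, tol = 1e-12, maxit = 500L) {
  x <- x0
  g <- gr(x)
  B <- diag(length(x))                     # inverse-Hessian approximation
  scale <- max(1, sqrt(sum(x0^2)))
  for (it in seq_len(maxit)) {
    if (sqrt(sum(g^2)) < tol * scale) break
    d <- -as.vector(B %*% g)
    if (sum(d * g) >= 0) { B <- diag(length(x)); d <- -g }
    Hd <- hvp(d)
    dHd <- sum(d * Hd)
    if (dHd <= 0) break
    alpha <- -sum(g * d) / dHd
    s <- alpha * d
    x <- x + s
    g_new <- gr(x)
    y <- g_new - g
    sy <- sum(s * y)
    if (sy > 1e-30) {
      By <- as.vector(B %*% y)
      B <- B + ((sy + sum(y * By)) / sy^2) * tcrossprod(s) -
        (tcrossprod(By, s) + tcrossprod(s, By)) / sy
    }
    g <- g_new
  }
  x
}

#' Exact block-tridiagonal solve of the smoothing problem
#'
#' Solves the normal equations of the Markov smoothing quadratic directly.
#' This is the independent verification path for [smooth_trajectory()]; the
#' two must agree to numerical precision.
#'
#' @inheritParams smooth_trajectory
#' @return n x 3 matrix of smoothed translations.
#' @export
smooth_trajectory_exact <- function(trajectory, confidence, transition,
                                    frame_rate = NULL) {
  tr <- as_la_trajectory(trajectory, frame_rate)
  reg <- tr$registrations
  n <- nrow(reg)
  Tp <- unname(as.matrix(reg[, c("tx", "ty", "tz")]))
  if (n == 1) return(Tp)
  e <- predict_error(confidence, reg$rho)
  sig2 <- e^2
  Sv_inv <- solve_pd(transition$Sigma_v)
  r2 <- tr$frame_rate^2
  A <- matrix(0, 3 * n, 3 * n)
  b <- numeric(3 * n)
  I3 <- diag(3)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    A[ii, ii] <- A[ii, ii] + I3 / sig2[i]
    b[ii] <- Tp[i, ] / sig2[i]
    if (i > 1) {
      jj <- (3 * (i - 1) - 2):(3 * (i - 1))
      A[ii, ii] <- A[ii, ii] + r2 * Sv_inv
      A[jj, jj] <- A[jj, jj] + r2 * Sv_inv
      A[ii, jj] <- A[ii, jj] - r2 * Sv_inv
      A[jj, ii] <- A[jj, ii] - r2 * Sv_inv
    }
  }
  matrix(solve(A, b), n, 3, byrow = TRUE)
}

#' Per-frame and summary error of a trajectory against ground truth
#'
#' @param estimates n x 3 matrix (or `la_trajectory` with `$filtered`).
#' @param truth `ground_truth` or n x 3 reference matrix; rows matched by
#'   `frames` when given.
#' @param frames Frame indices of the rows of `estimates`.
#' @return Tibble with `frame`, `error_mm`, plus attributes `mean_error` and
#'   `median_error`.
#' @export
evaluate_trajectory <- function(estimates, truth, frames = NULL) {
  X <- if (inherits(estimates, "la_trajectory")) {
    if (is.null(frames)) frames <- estimates$registrations$frame
    estimates$filtered %||% as.matrix(estimates$registrations[, c("tx", "ty", "tz")])
  } else as.matrix(estimates)
  ref <- if (inherits(truth, "ground_truth")) truth$translations else as.matrix(truth)
  if (is.null(frames)) frames <- seq_len(nrow(X))
  err <- sqrt(rowSums((X - ref[frames, , drop = FALSE])^2))
  out <- tibble::tibble(frame = as.integer(frames), error_mm = err)
  attr(out, "mean_error") <- mean(err)
  attr(out, "median_error") <- stats::median(err)
  out
}

#' Leave-one-sequence-out temporal filtering
#'
#' Trains the confidence regression and the transition covariance on all
#' sequences except the evaluated one, then filters it - so filtering
#' performance is never measured on its own training data.
#'
#' @param runs List; each element a list with `registrations` (a
#'   `frame_registrations` tibble including an `error_mm` column against that
#'   sequence's reference), `truth` (a `ground_truth`) and `frame_rate`.
#' @return List of `la_trajectory` objects with `$filtered` set, in input
#'   order.
#' @export
crossval_filter <- function(runs) {
  stopifnot(length(runs) >= 2)
  lapply(seq_along(runs), function(k) {
    train <- runs[-k]
    conf <- fit_confidence(dplyr::bind_rows(lapply(train, function(s)
      s$registrations[, c("rho", "error_mm")])))
    trans <- fit_transition(lapply(train, function(s)
      list(translations = s$truth$translations, frame_rate = s$frame_rate)))
    smooth_trajectory(runs[[k]]$registrations, conf, trans,
                      frame_rate = runs[[k]]$frame_rate)
  })
}
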