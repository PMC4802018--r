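# Scalar registration objectives. Every measure is a product of one
# normalized cross-correlation per plane; products of the shadow, apparent
# edge and CADE-consistency correlations and their alpha-weighted
# combinations with the edge term.

#' Normalized cross-correlation of two images
#'
#' Pearson correlation over all pixels:
#' `sum((I1 - mu1) (I2 - mu2)) / (N sigma1 sigma2)` with population
#' statistics, bounded in `[-1, 1]`. A constant image carries no information;
#' by convention the value is then 0 (logged, see [la_log_counters()]).
#'
#' @param I1,I2 Numeric matrices of equal shape.
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(I1, I2) {
  if (!all(dim(I1) == dim(I2))) stop("images must have the same shape")
  n <- length(I1)
  m1 <- mean(I1); m2 <- mean(I2)
  s1 <- sqrt(sum((I1 - m1)^2) / n)
  s2 <- sqrt(sum((I2 - m2)^2) / n)
  if (s1 == 0 || s2 == 0) { la_log_bump("ncc_zero_sigma"); return(0) }
  sum((I1 - m1) * (I2 - m2)) / (n * s1 * s2)
}

#' Similarity measure configuration
#'
#' @param measure One of `"shad_dsa"`, `"shad_thr"`, `"edge"`, `"cade"`,
#'   `"shad_dsa+edge"`, `"shad_thr+edge"`, `"cade+edge"`.
#' @param alpha Weight of the edge term in combined measures; equal weighting
#'   (`alpha = 1`) is the default.
#' @return Object of class `similarity_config`.
#' @export
similarity_config <- function(measure = "cade+edge", alpha = 1) {
  measure <- match.arg(measure, c("shad_dsa", "shad_thr", "edge", "cade",
                                  "shad_dsa+edge", "shad_thr+edge", "cade+edge"))
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  structure(list(measure = measure, alpha = alpha), class = "similarity_config")
}

# ---- cached evaluation context -------------------------------------------
# Registration evaluates hundreds of poses against fixed preprocessed images.
# The context precomputes, per plane: M %*% t(voxel centers) so translating
# the model is a vector add; image statistics for the O(active pixels) NCC
# fast path against binary renders; and mesh centroid/normal tables.

make_eval_context <- function(model, geometry, prepA = NULL, prepB = NULL) {
  shp <- geometry$image_shape
  mk_plane <- function(P, prep) {
    M <- P[, 1:3]; p4 <- P[, 4]
    V <- t(model_voxel_centers(model))          # 3 x N
    MV <- M %*% V                               # 3 x N
    fpx <- focal_px(P)
    ctr <- face_centroids(model$mesh)
    areas <- face_areas(model$mesh)
    keep <- areas > 1e-12
    if (!all(keep)) la_log_bump("degenerate_triangles", sum(!keep))
    Mctr <- M %*% t(ctr[keep, , drop = FALSE])
    env <- list(
      P = P, M = M, p4 = p4, fpx = fpx, voxel_mm = model$spacing,
      src = camera_center(P),
      ctr_world = ctr[keep, , drop = FALSE],
      nrm = model$mesh$normals[keep, , drop = FALSE],
      tri_size_mm = sqrt(2 * areas[keep]),
      Mctr = Mctr,
      project = function(t) {
        H <- MV + as.numeric(M %*% t) + p4
        list(u = H[1, ] / H[3, ], v = H[2, ] / H[3, ], w = H[3, ])
      },
      project_ctr = function(t) {
        H <- Mctr + as.numeric(M %*% t) + p4
        list(u = H[1, ] / H[3, ], v = H[2, ] / H[3, ], w = H[3, ])
      })
    if (!is.null(prep)) {
      addstats <- function(I) {
        mu <- mean(I); s <- sqrt(sum((I - mu)^2) / length(I))
        list(values = I, mu = mu, sigma = s)
      }
      env$thr <- addstats(prep$I_thr)
      env$dsa <- addstats(prep$I_DSA)
      env$dog <- addstats(prep$I_DOG)
      env$dog_sigma <- prep$params$dog_sigma
    }
    env
  }
  structure(list(A = mk_plane(geometry$P_A, prepA),
                 B = mk_plane(geometry$P_B, prepB),
                 shp = shp, model = model, geometry = geometry),
            class = "eval_context")
}

# NCC of a fixed image (precomputed stats) with a binary image given by the
# 1-based linear indices of its set pixels
ncc_binary_fast <- function(stats, idx, npix) {
  nS <- length(idx)
  if (nS == 0 || nS == npix) { la_log_bump("ncc_zero_sigma"); return(0) }
  if (stats$sigma == 0) { la_log_bump("ncc_zero_sigma"); return(0) }
  p <- nS / npix
  sigS <- sqrt(p * (1 - p))
  (sum(stats$values[idx]) - nS * stats$mu) / (npix * stats$sigma * sigS)
}

# full-image NCC against precomputed stats
ncc_stats <- function(stats, I) {
  n <- length(I)
  mu <- mean(I); s <- sqrt(sum((I - mu)^2) / n)
  if (s == 0 || stats$sigma == 0) { la_log_bump("ncc_zero_sigma"); return(0) }
  sum((stats$values - stats$mu) * (I - mu)) / (n * stats$sigma * s)
}

# per-plane shadow indices / cade indices / edge image at translation t
ctx_shadow_idx <- function(ctx, plane, t) shadow_indices(ctx[[plane]], t, ctx$shp)

ctx_cade <- function(ctx, t) {
  shp <- ctx$shp; npix <- shp[1] * shp[2]
  inA <- lookup_ctx(ctx$A, t, shp)
  inB <- lookup_ctx(ctx$B, t, shp)
  keep <- inA & inB
  list(keep = keep,
       idx_A = splat_subset(ctx$A, t, keep, shp),
       idx_B = splat_subset(ctx$B, t, keep, shp))
}

lookup_ctx <- function(pl, t, shp) {
  pr <- pl$project(t)
  u <- as.integer(round(pr$u)); v <- as.integer(round(pr$v))
  ok <- u >= 0L & u < shp[2] & v >= 0L & v < shp[1] & pr$w > 0
  out <- logical(length(u))
  if (any(ok)) out[ok] <- pl$thr$values[cbind(v[ok] + 1L, u[ok] + 1L)] > 0
  out
}

splat_subset <- function(pl, t, keep, shp) {
  if (!any(keep)) return(integer(0))
  pr <- pl$project(t)
  u <- as.integer(round(pr$u[keep])); v <- as.integer(round(pr$v[keep]))
  w <- pr$w[keep]
  size_px <- pmax(1L, as.integer(ceiling(pl$fpx * pl$voxel_mm / pmax(abs(w), 1e-6))))
  hit <- logical(shp[1] * shp[2])
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

ctx_edge_image <- function(ctx, plane, t) {
  pl <- ctx[[plane]]
  ctr <- sweep(pl$ctr_world, 2, t, "+")
  E <- edge_deposit(pl$P, pl$src, ctr, pl$nrm, ctx$shp, pl$tri_size_mm)
  sig <- pl$dog_sigma %||% 0
  if (sig > 0) E <- gauss_blur2(E, sig) else E
}

# ---- public measures ------------------------------------------------------

#' Shadow similarity measure
#'
#' Product over the two planes of the NCC between the projected model shadow
#' and either the signed subtraction image (`variant = "dsa"`) or the binary
#' contrast mask (`variant = "thr"`).
#'
#' @param prepA,prepB [preprocess_plane()] results for the two planes.
#' @param model An [atrium_model()].
#' @param geometry A [projection_geometry()].
#' @param T A [rigid_transform()] or length-3 translation (mm).
#' @param variant `"dsa"` or `"thr"`.
#' @param ctx Optional cached evaluation context (internal use).
#' @return Scalar similarity.
#' @export
rho_shadow <- function(prepA, prepB, model, geometry, T, variant = c("dsa", "thr"),
                       ctx = NULL) {
  variant <- match.arg(variant)
  if (is.null(ctx)) ctx <- make_eval_context(model, geometry, prepA, prepB)
  t <- as_translation(T)
  npix <- prod(ctx$shp)
  iA <- ctx_shadow_idx(ctx, "A", t)
  iB <- ctx_shadow_idx(ctx, "B", t)
  st <- if (variant == "thr") "thr" else "dsa"
  ncc_binary_fast(ctx$A[[st]], iA, npix) * ncc_binary_fast(ctx$B[[st]], iB, npix)
}

#' Apparent-edge similarity measure
#'
#' Product over the two planes of the NCC between the DOG edge image of the
#' fluoroscopic frame and the apparent-edge rendering of the transformed
#' mesh.
#'
#' @inheritParams rho_shadow
#' @param mesh Unused when `model` carries its mesh; kept for symmetry.
#' @return Scalar similarity.
#' @export
rho_edge <- function(prepA, prepB, model, geometry, T, ctx = NULL) {
  if (is.null(ctx)) ctx <- make_eval_context(model, geometry, prepA, prepB)
  t <- as_translation(T)
  EA <- ctx_edge_image(ctx, "A", t)
  EB <- ctx_edge_image(ctx, "B", t)
  ncc_stats(ctx$A$dog, EA) * ncc_stats(ctx$B$dog, EB)
}

#' CADE-consistency similarity measure
#'
#' Reconstructs the contrast-agent distribution estimate inside the chamber
#' at pose `T` ([compute_cade()]) and correlates its two forward projections
#' with the binary contrast masks.
#'
#' @inheritParams rho_shadow
#' @return Scalar similarity.
#' @export
rho_cade <- function(prepA, prepB, model, geometry, T, ctx = NULL) {
  if (is.null(ctx)) ctx <- make_eval_context(model, geometry, prepA, prepB)
  t <- as_translation(T)
  cd <- ctx_cade(ctx, t)
  npix <- prod(ctx$shp)
  ncc_binary_fast(ctx$A$thr, cd$idx_A, npix) * ncc_binary_fast(ctx$B$thr, cd$idx_B, npix)
}

#' Combined similarity measure
#'
#' Evaluates the measure named in `config`: a base measure, optionally plus
#' `alpha` times the edge measure.
#'
#' @inheritParams rho_shadow
#' @param config A [similarity_config()].
#' @return Scalar similarity.
#' @export
rho_combined <- function(prepA, prepB, model, geometry, T,
                         config = similarity_config(), ctx = NULL) {
  if (is.null(ctx)) ctx <- make_eval_context(model, geometry, prepA, prepB)
  parts <- strsplit(config$measure, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  val <- switch(base,
    shad_dsa = rho_shadow(ctx = ctx, T = T, variant = "dsa",
                          prepA = NULL, prepB = NULL, model = NULL, geometry = NULL),
    shad_thr = rho_shadow(ctx = ctx, T = T, variant = "thr",
                          prepA = NULL, prepB = NULL, model = NULL, geometry = NULL),
    cade = rho_cade(NULL, NULL, NULL, NULL, T, ctx = ctx),
    edge = 0)
  if (base == "edge" || length(parts) > 1) {
    e <- rho_edge(NULL, NULL, NULL, NULL, T, ctx = ctx)
    val <- if (base == "edge") e else val + config$alpha * e
  }
  val
}
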