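# Synthetic biplane angiography phantom: an atrium-like ellipsoidal chamber
# with tubular pulmonary veins, filled by contrast agent over time, breathing
# along the cranio-caudal axis, imaged by two pinhole cameras with known
# ground-truth translation per frame.

#' Phantom geometry specification
#'
#' Describes an atrium-like chamber: an ellipsoidal body with tubular
#' pulmonary veins attached to its surface, sampled on an isotropic voxel
#' grid centred on the world origin.
#'
#' @param body_radii Ellipsoid semi-axes (mm), length 3. Defaults approximate
#'   an adult left atrium (about 5-6 cm across).
#' @param pv_specs List of veins; each a list with `direction` (length-3,
#'   need not be unit), `radius` (mm) and `length` (mm). The default four
#'   veins leave the posterior aspect of the body superiorly and inferiorly on
#'   both sides.
#' @param voxel_spacing Isotropic voxel size (mm).
#' @param grid_shape Voxel grid extents, length 3.
#' @param seed Integer seed driving every random element downstream.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_radii = c(28, 22, 25),
                         pv_specs = default_pv_specs(),
                         voxel_spacing = 2,
                         grid_shape = c(64L, 64L, 64L),
                         seed = 1L) {
  if (any(body_radii <= 0)) stop("body_radii must be positive")
  if (voxel_spacing <= 0) stop("voxel_spacing must be positive")
  structure(list(body_radii = as.numeric(body_radii),
                 pv_specs = pv_specs,
                 voxel_spacing = voxel_spacing,
                 grid_shape = as.integer(grid_shape),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

default_pv_specs <- function() {
  dirs <- list(c(-0.75, 0.45, 0.5), c(0.75, 0.45, 0.5),
               c(-0.75, 0.45, -0.5), c(0.75, 0.45, -0.5))
  lapply(dirs, function(d) list(direction = d, radius = 5.5, length = 22))
}

#' Build the 3D chamber model from a phantom specification
#'
#' Rasterizes the union of the ellipsoidal body and the cylindrical veins on
#' the voxel grid, repairs checkerboard configurations so the surface is
#' edge-manifold, and extracts a closed triangle mesh with smoothed outward
#' normals. The voxel indicator and the mesh describe exactly the same solid.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `atrium_model` with fields `volume` (logical
#'   array), `spacing` (mm), `origin` (world position of the centre of voxel
#'   (1,1,1)), and `mesh` (a [triangle_mesh()]).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  origin <- -(d - 1) / 2 * sp
  xs <- origin[1] + (seq_len(d[1]) - 1) * sp
  ys <- origin[2] + (seq_len(d[2]) - 1) * sp
  zs <- origin[3] + (seq_len(d[3]) - 1) * sp

  a <- spec$body_radii
  X2 <- (xs / a[1])^2; Y2 <- (ys / a[2])^2; Z2 <- (zs / a[3])^2
  A <- outer(outer(X2, Y2, "+"), Z2, "+") <= 1

  lo <- origin - sp / 2
  hi <- origin + (d - 1) * sp + sp / 2
  for (vi in seq_along(spec$pv_specs)) {
    pv <- spec$pv_specs[[vi]]
    dir <- pv$direction / sqrt(sum(pv$direction^2))
    tt <- 1 / sqrt(sum((dir / a)^2))          # ray-ellipsoid exit distance
    o <- tt * dir                              # attachment point on the surface
    endp <- o + pv$length * dir
    if (any(endp - pv$radius < lo) || any(endp + pv$radius > hi))
      stop(sprintf("vein %d extends outside the voxel grid", vi))
    A <- A | cylinder_mask(xs, ys, zs, o - 2 * dir, dir, pv$radius, pv$length + 2)
  }

  A <- make_well_composed(A)
  mesh <- extract_surface(A, sp, origin)
  mesh <- smooth_mesh_normals(mesh, A, sp, origin)
  model <- atrium_model(A, sp, origin, mesh)
  model$pv_tips <- lapply(spec$pv_specs, function(pv) {
    dir <- pv$direction / sqrt(sum(pv$direction^2))
    tt <- 1 / sqrt(sum((dir / spec$body_radii)^2))
    tt * dir + (pv$length - pv$radius) * dir
  })
  model
}

cylinder_mask <- function(xs, ys, zs, o, dir, radius, len) {
  d <- c(length(xs), length(ys), length(zs))
  # s = (p - o) . dir, computed separably
  sx <- (xs - o[1]) * dir[1]; sy <- (ys - o[2]) * dir[2]; sz <- (zs - o[3]) * dir[3]
  S <- outer(outer(sx, sy, "+"), sz, "+")
  # |p - o|^2 separably
  qx <- (xs - o[1])^2; qy <- (ys - o[2])^2; qz <- (zs - o[3])^2
  Q <- outer(outer(qx, qy, "+"), qz, "+")
  R2 <- Q - S^2
  S >= 0 & S <= len & R2 <= radius^2
}

#' Atrium model container
#'
#' @param volume Logical 3D array: the inside-chamber indicator on the voxel
#'   grid.
#' @param spacing Isotropic voxel size (mm).
#' @param origin World coordinates (mm) of the centre of voxel (1,1,1).
#' @param mesh Closed [triangle_mesh()] of the chamber surface.
#' @return Object of class `atrium_model`.
#' @export
atrium_model <- function(volume, spacing, origin, mesh) {
  stopifnot(is.logical(volume), length(dim(volume)) == 3L)
  structure(list(volume = volume, spacing = spacing, origin = as.numeric(origin),
                 mesh = mesh),
            class = "atrium_model")
}

#' @export
print.atrium_model <- function(x, ...) {
  cat(sprintf("<atrium_model> %s voxels at %.2f mm, %d inside, %d faces\n",
              paste(dim(x$volume), collapse = "x"), x$spacing,
              sum(x$volume), nrow(x$mesh$faces)))
  invisible(x)
}

# world coordinates (N x 3) of all inside voxels, cached on first use
model_voxel_centers <- function(model) {
  if (!is.null(model$.centers)) return(model$.centers)
  w <- which(model$volume, arr.ind = TRUE)
  sweep((w - 1) * model$spacing, 2, model$origin, "+")
}

#' Contrast injection scenario
#'
#' Describes how contrast agent appears over the frames of a synthetic
#' sequence: where it is injected, how much of the chamber volume is
#' opacified in each frame, when it washes out into the ventricle, plus
#' breathing motion, acquisition artifacts and noise.
#'
#' @param site Injection site: `"center"`, a vein index (integer), or a world
#'   point (length-3 numeric, mm).
#' @param fill_fractions Per-frame fraction in `[0, 1]` of the chamber volume
#'   opacified; must be non-decreasing up to `ejection_frame`. Frames with
#'   fraction 0 are annotated uncontrasted.
#' @param ejection_frame Frame index after which contrast decays (washout);
#'   `Inf` for none.
#' @param breathing_amplitude Cranio-caudal breathing amplitude (mm).
#' @param breathing_period Breathing period in frames.
#' @param artifact_flags Named logical list: `catheter`, `diaphragm`,
#'   `brightness_drift`.
#' @param noise_sd Additive Gaussian noise standard deviation (12-bit
#'   intensity units).
#' @param frame_rate Acquisition frame rate (frames/s).
#' @return Object of class `injection_scenario`.
#' @export
injection_scenario <- function(site = "center",
                               fill_fractions = c(0, 0, 0, seq(0.15, 1, length.out = 9)),
                               ejection_frame = Inf,
                               breathing_amplitude = 4,
                               breathing_period = 12,
                               artifact_flags = list(catheter = TRUE, diaphragm = TRUE,
                                                     brightness_drift = FALSE),
                               noise_sd = 6,
                               frame_rate = 7.5) {
  ff <- as.numeric(fill_fractions)
  if (any(ff < 0 | ff > 1)) stop("fill fractions must lie in [0, 1]")
  upto <- ff[seq_len(min(length(ff), ejection_frame))]
  if (any(diff(upto) < -1e-12))
    stop("fill_fractions must be non-decreasing up to ejection_frame")
  structure(list(site = site, fill_fractions = ff, ejection_frame = ejection_frame,
                 breathing_amplitude = breathing_amplitude,
                 breathing_period = breathing_period,
                 artifact_flags = modifyList(
                   list(catheter = FALSE, diaphragm = FALSE, brightness_drift = FALSE),
                   artifact_flags),
                 noise_sd = noise_sd, frame_rate = frame_rate),
            class = "injection_scenario")
}

#' Preset: central injection (transseptal-puncture check)
#'
#' Emulates a 15 mL injection into the chamber centre: contrast spreads from
#' the centre and opacifies the whole chamber.
#' @param n_pre Number of uncontrasted lead-in frames.
#' @param n_fill Number of contrasted frames.
#' @param ... Passed to [injection_scenario()].
#' @export
scenario_center_injection <- function(n_pre = 3, n_fill = 9, ...) {
  injection_scenario(site = "center",
                     fill_fractions = c(rep(0, n_pre),
                                        seq(0.2, 1, length.out = n_fill)), ...)
}

#' Preset: pulmonary-vein injection (catheter-placement check)
#'
#' Emulates a smaller (about 10 mL) injection into a vein: contrast opacifies
#' the vein first and only part of the chamber body, the regime in which
#' shadow-only similarity measures become ambiguous.
#' @param vein Vein index into the phantom's `pv_specs`.
#' @param max_fill Final opacified volume fraction.
#' @param n_pre,n_fill Frame counts as in [scenario_center_injection()].
#' @param ... Passed to [injection_scenario()].
#' @export
scenario_vein_injection <- function(vein = 1L, max_fill = 0.35, n_pre = 3, n_fill = 9, ...) {
  injection_scenario(site = as.integer(vein),
                     fill_fractions = c(rep(0, n_pre),
                                        seq(0.05, max_fill, length.out = n_fill)), ...)
}

# geodesic (6-connected BFS) distance inside the chamber from the injection
# seed; used to grow the filled region so a vein injection opacifies the vein
# first. Returns an integer array, NA outside chi or unreachable.
geodesic_distance <- function(volume, seed_idx) {
  d <- dim(volume)
  dist <- array(NA_integer_, d)
  cur <- array(FALSE, d)
  cur[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  if (!volume[seed_idx[1], seed_idx[2], seed_idx[3]])
    stop("injection site lies outside the chamber")
  dist[cur] <- 0L
  level <- 0L
  visited <- cur
  while (any(cur)) {
    level <- level + 1L
    nxt <- shift3(cur, 1, 1) | shift3(cur, 1, -1) |
           shift3(cur, 2, 1) | shift3(cur, 2, -1) |
           shift3(cur, 3, 1) | shift3(cur, 3, -1)
    nxt <- nxt & volume & !visited
    if (!any(nxt)) break
    dist[nxt] <- level
    visited <- visited | nxt
    cur <- nxt
  }
  dist
}

resolve_injection_site <- function(model, site) {
  d <- dim(model$volume)
  if (is.character(site) && site == "center") {
    idx <- round((c(0, 0, 0) - model$origin) / model$spacing) + 1
  } else if (is.numeric(site) && length(site) == 1L) {
    if (is.null(model$pv_tips) || site > length(model$pv_tips))
      stop("model carries no vein tip for site index ", site)
    idx <- round((model$pv_tips[[site]] - model$origin) / model$spacing) + 1
  } else if (is.numeric(site) && length(site) == 3L) {
    idx <- round((site - model$origin) / model$spacing) + 1
  } else stop("unrecognized injection site")
  idx <- pmin(pmax(as.integer(idx), 1L), d)
  # snap to the nearest inside voxel if the rounded index fell outside chi
  if (!model$volume[idx[1], idx[2], idx[3]]) {
    centers <- model_voxel_centers(model)
    p <- model$origin + (idx - 1) * model$spacing
    k <- which.min(colSums((t(centers) - p)^2))
    w <- which(model$volume, arr.ind = TRUE)
    idx <- as.integer(w[k, ])
  }
  idx
}

#' Simulate a biplane contrast-injection sequence with ground truth
#'
#' Renders per-frame X-ray attenuation by summing the contrasted-voxel
#' indicator along projection rays (a binary-mask line integral with constant
#' contrast density), subtracted from a smooth background. The filled region
#' grows by geodesic dilation from the injection site inside the chamber, so
#' vein injections opacify the vein first. Breathing translates the chamber
#' along the cranio-caudal axis by `amplitude * sin(2*pi*(frame-1)/period)`.
#' Optional artifacts: a dark catheter curve whose position differs between
#' frames, a diaphragm half-plane ramp that moves with breathing, and a
#' per-frame brightness drift. All randomness is driven by `seed`.
#'
#' @param model An [atrium_model()] from [build_phantom()].
#' @param scenario An [injection_scenario()].
#' @param geometry A [projection_geometry()].
#' @param seed Integer seed; defaults to the phantom seed convention 1.
#' @return List with `sequence` (a `biplane_sequence`) and `truth` (a
#'   `ground_truth`: per-frame true translation matrix `translations` and the
#'   per-frame contrasted-voxel masks, stored compactly as a fill order plus
#'   per-frame counts).
#' @export
simulate_sequence <- function(model, scenario, geometry, seed = 1L) {
  stopifnot(inherits(model, "atrium_model"),
            inherits(scenario, "injection_scenario"),
            inherits(geometry, "projection_geometry"))
  n <- length(scenario$fill_fractions)
  shp <- geometry$image_shape
  with_seed(seed, {
    seed_idx <- resolve_injection_site(model, scenario$site)
    dist <- geodesic_distance(model$volume, seed_idx)
    inside <- which(model$volume)
    dvals <- dist[inside]
    dvals[is.na(dvals)] <- max(dvals, na.rm = TRUE) + 1L  # unreachable last
    fill_order <- inside[order(dvals, inside)]            # deterministic
    n_inside <- length(inside)

    # per-frame opacified voxel counts; washout shrinks from the far end
    fracs <- scenario$fill_fractions
    if (is.finite(scenario$ejection_frame) && scenario$ejection_frame < n) {
      post <- (scenario$ejection_frame + 1):n
      decay <- 0.6 ^ seq_along(post)
      fracs[post] <- fracs[scenario$ejection_frame] * decay
    }
    counts <- round(fracs * n_inside)

    # ground-truth breathing translation (zero mean over whole cycles)
    phase <- 2 * pi * (seq_len(n) - 1) / scenario$breathing_period
    truth_t <- cbind(0, 0, scenario$breathing_amplitude * sin(phase))

    centers <- model_voxel_centers(model)
    rownames(centers) <- NULL
    lin <- which(model$volume)
    pos_of <- match(fill_order, lin)          # rows of `centers` in fill order

    # background: gentle planar ramp around 2000 (12-bit scale)
    base_bg <- function(shp) {
      rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
      cc <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
      2000 + 100 * (rr / shp[1] - 0.5) + 60 * (cc / shp[2] - 0.5)
    }
    bgA <- base_bg(shp); bgB <- base_bg(shp)

    # fixed attenuation scaling: full-fill projection at the rest pose
    k_scale <- local({
      full <- render_attenuation(centers, geometry$P_A, shp, model$spacing)
      1200 / max(max(full), 1)
    })

    cath_base <- runif(2, 0.3, 0.7)           # per-plane catheter anchor
    framesA <- vector("list", n); framesB <- vector("list", n)
    contrasted <- fracs > 0
    for (i in seq_len(n)) {
      filled_rows <- if (counts[i] > 0) pos_of[seq_len(counts[i])] else integer(0)
      pts <- centers[filled_rows, , drop = FALSE]
      pts <- sweep(pts, 2, truth_t[i, ], "+")
      for (pl in 1:2) {
        P <- if (pl == 1) geometry$P_A else geometry$P_B
        bg <- if (pl == 1) bgA else bgB
        att <- if (nrow(pts)) render_attenuation(pts, P, shp, model$spacing)
               else matrix(0, shp[1], shp[2])
        img <- bg - k_scale * att
        if (scenario$artifact_flags$catheter)
          img <- img - catheter_curve(shp, cath_base[pl] + 0.02 * sin(1.7 * i) +
                                        runif(1, -0.01, 0.01))
        if (scenario$artifact_flags$diaphragm) {
          v0 <- shp[1] * (0.78 + 0.04 * sin(phase[i]))
          rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
          img <- img - 350 / (1 + exp(-(rr - v0) / (0.02 * shp[1])))
        }
        if (scenario$artifact_flags$brightness_drift)
          img <- img + 15 * (i - 1)
        if (scenario$noise_sd > 0)
          img <- img + matrix(rnorm(prod(shp), 0, scenario$noise_sd), shp[1], shp[2])
        img <- round(pmin(pmax(img, 0), 4095))
        if (pl == 1) framesA[[i]] <- img else framesB[[i]] <- img
      }
    }

    seqc <- biplane_sequence(framesA, framesB, contrasted, scenario$frame_rate,
                             geometry, intensity_range = 4095)
    truth <- structure(list(translations = truth_t,
                            fill_order = fill_order,
                            fill_counts = counts,
                            grid_dim = dim(model$volume)),
                       class = "ground_truth")
    list(sequence = seqc, truth = truth)
  })
}

# additive splat of points into the detector raster: per-pixel voxel counts,
# each voxel spread over its projected square footprint
render_attenuation <- function(pts, P, shp, voxel_mm) {
  splat_points(P, pts, shp, voxel_mm, counts = TRUE)
}

catheter_curve <- function(shp, x_frac) {
  rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
  cc <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
  xc <- x_frac * shp[2] + 0.06 * shp[2] * sin(6 * rr / shp[1])
  w <- 0.008 * shp[2] + 1
  300 * exp(-((cc - xc)^2) / (2 * w^2))
}

#' Biplane sequence container
#'
#' @param frames_A,frames_B Lists of numeric matrices (one per frame).
#' @param contrasted Logical per-frame annotation.
#' @param frame_rate Frames per second.
#' @param geometry A [projection_geometry()].
#' @param intensity_range Maximum representable intensity (e.g. 4095 for
#'   12-bit); used to scale the sigmoid slope.
#' @return Object of class `biplane_sequence`.
#' @export
biplane_sequence <- function(frames_A, frames_B, contrasted, frame_rate,
                             geometry, intensity_range = 4095) {
  if (length(frames_A) != length(frames_B))
    stop("plane A and plane B must have the same number of frames")
  if (length(contrasted) != length(frames_A))
    stop("annotation must cover every frame")
  structure(list(frames_A = frames_A, frames_B = frames_B,
                 contrasted = as.logical(contrasted),
                 frame_rate = frame_rate, geometry = geometry,
                 intensity_range = intensity_range),
            class = "biplane_sequence")
}

#' @export
print.biplane_sequence <- function(x, ...) {
  cat(sprintf("<biplane_sequence> %d frames (%d contrasted), %.1f fps, %dx%d px\n",
              length(x$frames_A), sum(x$contrasted), x$frame_rate,
              x$geometry$image_shape[1], x$geometry$image_shape[2]))
  invisible(x)
}

#' Per-frame contrasted-voxel mask from a ground-truth object
#'
#' @param truth A `ground_truth` from [simulate_sequence()].
#' @param frame Frame index.
#' @return Logical 3D array on the model grid.
#' @export
truth_fill_mask <- function(truth, frame) {
  A <- array(FALSE, truth$grid_dim)
  cnt <- truth$fill_counts[frame]
  if (cnt > 0) A[truth$fill_order[seq_len(cnt)]] <- TRUE
  A
}
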