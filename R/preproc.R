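# Contrast extraction and edge preprocessing for one detector plane: choose
# the uncontrasted reference that minimizes the L1 norm of the subtraction
# image, clamp and median-filter the DSA, threshold at mu + sigma, homogenize
# with a sigmoid centred one sigma below the mean, and take the
# derivative-of-Gaussian edge magnitude.

#' Best-reference selection for digital subtraction angiography
#'
#' Among all uncontrasted candidate frames, selects the one minimizing the L1
#' norm of the subtraction image `sum |I_u - I_c|`, so that catheters and the
#' diaphragm cancel out as much as possible. Ties are broken by the lowest
#' index.
#'
#' @param uncontrasted_frames List of numeric matrices (candidate references).
#' @param I_c Contrasted frame, numeric matrix of the same shape.
#' @return List with `index` of the selected reference and the subtraction
#'   image `I_DSA = I_u_hat - I_c` (positive where contrast attenuates).
#' @export
select_reference <- function(uncontrasted_frames, I_c) {
  if (length(uncontrasted_frames) == 0)
    stop("need at least one uncontrasted candidate frame")
  for (f in uncontrasted_frames)
    if (!all(dim(f) == dim(I_c))) stop("candidate frame shape differs from I_c")
  l1 <- vapply(uncontrasted_frames, function(f) sum(abs(f - I_c)), numeric(1))
  idx <- which.min(l1)                     # which.min takes the first minimum
  list(index = idx, I_DSA = uncontrasted_frames[[idx]] - I_c)
}

#' Extract the contrasted area from a DSA image
#'
#' Negative pixels (contrast only attenuates) are clamped to zero; a square
#' median filter with a large kernel removes residual motion artifacts and
#' noise; the binary contrast mask thresholds the filtered image strictly
#' above `mu_f + sigma_f` (mean and standard deviation over all pixels).
#'
#' @param I_DSA Signed subtraction image.
#' @param median_kernel Full width of the median window in px (made odd by
#'   rounding up); the reference value is 30 px at 1024-px image width.
#' @return List `I_f` (filtered non-negative image), `mu_f`, `sigma_f`,
#'   `I_thr` (binary mask).
#' @export
extract_contrast <- function(I_DSA, median_kernel = 30) {
  I_pos <- pmax(I_DSA, 0)
  width <- ceiling(median_kernel)
  if (width %% 2 == 0) width <- width + 1
  radius <- (width - 1) / 2
  I_f <- if (radius >= 1) median_filter_reflect(I_pos, radius) else I_pos
  mu_f <- mean(I_f)
  sigma_f <- stats::sd(as.vector(I_f)) * sqrt((length(I_f) - 1) / length(I_f))
  I_thr <- (I_f > mu_f + sigma_f) * 1
  list(I_f = I_f, mu_f = mu_f, sigma_f = sigma_f, I_thr = I_thr)
}

# EBImage constant-time median filter works on [0,1]; scale, reflect-pad by
# the radius, filter, crop, rescale.
median_filter_reflect <- function(X, radius) {
  mx <- max(X)
  if (mx <= 0) return(X)
  n <- nrow(X); m <- ncol(X)
  ri <- c(pmin(radius:1 + 1, n), 1:n, pmax(n - (1:radius), 1))
  ci <- c(pmin(radius:1 + 1, m), 1:m, pmax(m - (1:radius), 1))
  Xp <- X[ri, ci] / mx
  Y <- EBImage::medianFilter(Xp, radius)
  Y[radius + (1:n), radius + (1:m)] * mx
}

#' Sigmoid intensity homogenization
#'
#' Maps the filtered contrast image through
#' `I_sig = 1 / (1 + exp(-(I_f - t) * s))` with midpoint `t = mu_f - sigma_f`,
#' flattening the intensity distribution inside the contrasted area while
#' keeping the drop-off at its boundary. The slope `s` is 0.1 for 12-bit
#' input and scales inversely with the intensity range.
#'
#' @param I_f Filtered non-negative image.
#' @param mu_f,sigma_f Statistics of `I_f` as returned by
#'   [extract_contrast()].
#' @param s Sigmoid slope (per intensity unit).
#' @return Matrix with values in (0, 1).
#' @export
sigmoid_homogenize <- function(I_f, mu_f, sigma_f, s = 0.1) {
  t0 <- mu_f - sigma_f
  1 / (1 + exp(-(I_f - t0) * s))
}

#' Derivative-of-Gaussian edge magnitude
#'
#' Euclidean magnitude of the two first-order Gaussian-derivative responses.
#' A large scale is used so the downstream similarity measure is smooth; the
#' reference value is 24 px at 1024-px image width.
#'
#' @param I_sig Input image (typically the sigmoid-homogenized one).
#' @param dog_sigma Gaussian scale in px.
#' @return Non-negative edge-magnitude matrix.
#' @export
dog_edges <- function(I_sig, dog_sigma = 24) {
  n <- nrow(I_sig); m <- ncol(I_sig)
  Gr  <- gauss_matrix(n, dog_sigma)
  Gc  <- gauss_matrix(m, dog_sigma)
  Dr  <- gauss_matrix(n, dog_sigma, deriv = TRUE)
  Dc  <- gauss_matrix(m, dog_sigma, deriv = TRUE)
  gx <- Gr %*% I_sig %*% t(Dc)    # derivative along columns (u)
  gy <- Dr %*% I_sig %*% t(Gc)    # derivative along rows (v)
  sqrt(gx^2 + gy^2)
}

#' Preprocess one plane of a sequence for a given contrasted frame
#'
#' Runs the full chain: best-reference DSA, contrast extraction, sigmoid
#' homogenization and DOG edges. Pixel-unit parameters (`median_kernel`,
#' `dog_sigma`) are specified at the 1024-px reference width and scaled
#' linearly to the actual image width; the sigmoid slope is scaled to the
#' sequence's intensity range (0.1 at 12 bit).
#'
#' @param sequence A [biplane_sequence()].
#' @param frame Index of the contrasted frame to preprocess.
#' @param plane `"A"` or `"B"`.
#' @param median_kernel,dog_sigma Pixel-unit parameters at 1024-px width.
#' @param s Sigmoid slope at 12-bit range.
#' @return Object of class `preprocessed_plane` with fields `I_DSA`,
#'   `reference_index`, `I_f`, `mu_f`, `sigma_f`, `I_thr`, `I_sig`, `I_DOG`
#'   and `params`.
#' @export
preprocess_plane <- function(sequence, frame, plane = c("A", "B"),
                             median_kernel = 30, dog_sigma = 24, s = 0.1) {
  plane <- match.arg(plane)
  stopifnot(inherits(sequence, "biplane_sequence"))
  if (!sequence$contrasted[frame])
    stop("frame ", frame, " is annotated uncontrasted")
  frames <- if (plane == "A") sequence$frames_A else sequence$frames_B
  I_c <- frames[[frame]]
  cand_idx <- which(!sequence$contrasted)
  if (!length(cand_idx)) stop("sequence contains no uncontrasted frames")
  ref <- select_reference(frames[cand_idx], I_c)

  scale <- ncol(I_c) / 1024
  mk <- median_kernel * scale
  ds <- dog_sigma * scale
  s_eff <- s * 4096 / (sequence$intensity_range + 1)

  ec <- extract_contrast(ref$I_DSA, mk)
  I_sig <- sigmoid_homogenize(ec$I_f, ec$mu_f, ec$sigma_f, s_eff)
  I_DOG <- dog_edges(I_sig, ds)
  structure(list(I_DSA = ref$I_DSA,
                 reference_index = cand_idx[ref$index],
                 I_f = ec$I_f, mu_f = ec$mu_f, sigma_f = ec$sigma_f,
                 I_thr = ec$I_thr, I_sig = I_sig, I_DOG = I_DOG,
                 params = list(median_kernel = mk, sigmoid_s = s_eff,
                               sigmoid_t = ec$mu_f - ec$sigma_f,
                               dog_sigma = ds)),
            class = "preprocessed_plane")
}

#' @export
print.preprocessed_plane <- function(x, ...) {
  cat(sprintf("<preprocessed_plane> %dx%d px, ref frame %d, %d contrasted px (%.1f%%)\n",
              nrow(x$I_DSA), ncol(x$I_DSA), x$reference_index,
              sum(x$I_thr), 100 * mean(x$I_thr)))
  invisible(x)
}
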