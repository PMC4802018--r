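# broom-style accessors and ggplot2 autoplot methods for the tabular result
# objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a smoothed trajectory
#'
#' @param x An `la_trajectory`.
#' @param ... Unused.
#' @return Tibble with one row per frame: unfiltered estimate (`tx`, `ty`,
#'   `tz`), similarity `rho`, and when filtering has been run the filtered
#'   translation (`tx_filtered`, ...).
#' @method tidy la_trajectory
#' @export
tidy.la_trajectory <- function(x, ...) {
  out <- tibble::as_tibble(x$registrations)
  if (!is.null(x$filtered)) {
    out$tx_filtered <- x$filtered[, 1]
    out$ty_filtered <- x$filtered[, 2]
    out$tz_filtered <- x$filtered[, 3]
  }
  out
}

#' One-row summary of a smoothed trajectory
#'
#' @param x An `la_trajectory`.
#' @param ... Unused.
#' @return Tibble with frame count, frame rate, mean similarity and mean
#'   state standard deviation.
#' @method glance la_trajectory
#' @export
glance.la_trajectory <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$registrations),
                 frame_rate = x$frame_rate,
                 mean_rho = mean(x$registrations$rho),
                 mean_state_sd_mm = if (!is.null(x$Sigma_diag))
                   mean(sqrt(x$Sigma_diag)) else NA_real_)
}

#' Tidy a confidence regression
#'
#' @param x A `confidence_model`.
#' @param ... Unused.
#' @return Tibble of terms and estimates (broom layout).
#' @method tidy confidence_model
#' @export
tidy.confidence_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "rho"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance confidence_model
#' @export
glance.confidence_model <- function(x, ...) {
  tibble::tibble(floor_mm = x$floor)
}

#' Plot a trajectory's translation components over frames
#'
#' Unfiltered estimates as points, the Markov-filtered trajectory as lines.
#'
#' @param object An `la_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot la_trajectory
#' @export
autoplot.la_trajectory <- function(object, ...) {
  df <- tidy.la_trajectory(object)
  long <- do.call(rbind, lapply(c("tx", "ty", "tz"), function(ax) {
    data.frame(frame = df$frame, axis = ax, raw = df[[ax]],
               filtered = if (!is.null(object$filtered))
                 df[[paste0(ax, "_filtered")]] else NA_real_)
  }))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw), shape = 1) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "translation (mm)")
  if (!is.null(object$filtered))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$filtered), colour = "#2166ac")
  p
}

#' Plot per-frame registration similarity values
#'
#' @param object A `frame_registrations` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frame_registrations
#' @export
autoplot.frame_registrations <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frame, y = .data$rho)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "frame", y = expression(rho))
}

#' @importFrom rlang .data
NULL
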