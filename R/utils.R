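#' @importFrom stats rnorm runif sd quantile optim lm coef predict
#' @importFrom utils modifyList head tail
NULL

# package-level event log: counters for numerically degenerate events that the
# similarity and rendering code handles silently (zero-variance NCC, discarded
# non-finite objective cells, degenerate triangles).
.atriareg_log <- new.env(parent = emptyenv())

la_log_reset <- function() {
  rm(list = ls(.atriareg_log), envir = .atriareg_log)
  invisible(NULL)
}

la_log_bump <- function(event, n = 1L) {
  cur <- if (exists(event, envir = .atriareg_log)) get(event, envir = .atriareg_log) else 0L
  assign(event, cur + n, envir = .atriareg_log)
  invisible(NULL)
}

#' Counters of degenerate numerical events since the last reset
#'
#' The rendering and similarity code copes with degenerate situations
#' (an all-constant image in a correlation, a non-finite objective value at a
#' search cell, a zero-area triangle) by well-defined fallbacks rather than
#' errors. Each occurrence is counted here so that pipeline reports can expose
#' them.
#'
#' @return Named integer vector of event counts (possibly empty).
#' @export
la_log_counters <- function() {
  keys <- sort(ls(.atriareg_log))
  vapply(keys, function(k) get(k, envir = .atriareg_log), integer(1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic package code funnels through
# this so that a scenario seed fully determines the output.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}
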