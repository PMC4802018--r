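# File interfaces: NIfTI volumes + ASCII STL meshes for the chamber model,
# multi-page TIFF + JSON sidecar for biplane sequences, JSON for geometry,
# transforms and reports, and the end-to-end pipeline runner.

#' Write a projection geometry to JSON
#'
#' Stores the two 3x4 matrices row-major, the raster shape and the pixel
#' spacing; human-diffable.
#'
#' @param geometry A [projection_geometry()].
#' @param path Output path.
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(list(
    P_A = as.vector(t(geometry$P_A)), P_B = as.vector(t(geometry$P_B)),
    image_shape = geometry$image_shape, pixel_spacing = geometry$pixel_spacing
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projection geometry from JSON
#'
#' @param path JSON file written by [write_geometry()].
#' @return A [projection_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  projection_geometry(matrix(j$P_A, 3, 4, byrow = TRUE),
                      matrix(j$P_B, 3, 4, byrow = TRUE),
                      j$image_shape, j$pixel_spacing)
}

#' Write an atrium model (volume + mesh)
#'
#' Writes the binary indicator volume as NIfTI (with mm spacing) and the
#' surface mesh as ASCII STL next to it.
#'
#' @param model An [atrium_model()].
#' @param prefix Path prefix; writes `<prefix>.nii.gz` and `<prefix>.stl`.
#' @export
write_model <- function(model, prefix) {
  vol <- RNifti::asNifti(array(as.numeric(model$volume), dim(model$volume)))
  RNifti::pixdim(vol) <- rep(model$spacing, 3)
  RNifti::writeNifti(vol, paste0(prefix, ".nii.gz"))
  write_stl(model$mesh, paste0(prefix, ".stl"))
  invisible(prefix)
}

#' Read an atrium model from a mesh or volume file
#'
#' Both representations are always populated: an STL mesh is voxelized at
#' `spacing` (refused with a diagnostic if it is not watertight); a NIfTI
#' volume is thresholded at 0.5 and a closed surface extracted from it.
#'
#' @param path `.stl`, `.nii` or `.nii.gz` file.
#' @param spacing Voxel spacing (mm) used when voxelizing a mesh; for a
#'   volume the spacing is read from the header.
#' @param margin_mm Grid margin around a mesh's bounding box.
#' @return An [atrium_model()].
#' @export
read_model <- function(path, spacing = 2, margin_mm = 6) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "stl") {
    mesh <- read_stl(path)
    # offset the sampling grid by half a voxel plus a distinct hair per axis,
    # so ray casting through voxel-centre columns never passes exactly
    # through mesh vertices, axis-aligned edges or triangle diagonals
    lo <- apply(mesh$vertices, 2, min) - margin_mm + 0.5 * spacing +
      c(1.7e-4, 2.9e-4, 0.7e-4)
    hi <- apply(mesh$vertices, 2, max) + margin_mm
    d <- pmax(ceiling((hi - lo) / spacing) + 1, 4)
    A <- voxelize_mesh(mesh, spacing, d, lo)
    A <- make_well_composed(A)
    atrium_model(A, spacing, lo, mesh)
  } else if (ext %in% c("nii", "img", "hdr")) {
    vol <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(vol)[1]
    A <- array(as.array(vol) > 0.5, dim(vol))
    A <- make_well_composed(A)
    origin <- -(dim(A) - 1) / 2 * sp
    mesh <- smooth_mesh_normals(extract_surface(A, sp, origin), A, sp, origin)
    atrium_model(A, sp, origin, mesh)
  } else stop("unsupported model format: ", path)
}

#' Write a biplane sequence (multi-page TIFF per plane + JSON sidecar)
#'
#' Intensities are stored as 16-bit TIFF; the sidecar records the intensity
#' range, per-frame contrast annotations, the frame rate, the geometry and,
#' when given, the ground-truth translations, so a phantom round-trips
#' losslessly.
#'
#' @param sequence A [biplane_sequence()].
#' @param dir Output directory (created if missing).
#' @param truth Optional `ground_truth` whose translations go into the
#'   sidecar.
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(sequence, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(frames, path)
    tiff::writeTIFF(lapply(frames, function(f) f / 65535), path,
                    bits.per.sample = 16L)
  wr(sequence$frames_A, file.path(dir, "planeA.tif"))
  wr(sequence$frames_B, file.path(dir, "planeB.tif"))
  side <- list(contrasted = sequence$contrasted,
               frame_rate = sequence$frame_rate,
               intensity_range = sequence$intensity_range,
               geometry = list(P_A = as.vector(t(sequence$geometry$P_A)),
                               P_B = as.vector(t(sequence$geometry$P_B)),
                               image_shape = sequence$geometry$image_shape,
                               pixel_spacing = sequence$geometry$pixel_spacing))
  if (!is.null(truth)) side$truth_translations <- truth$translations
  jsonlite::write_json(side, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a biplane sequence written by [write_sequence()]
#'
#' Validates equal frame counts across planes and complete annotation
#' coverage.
#'
#' @param dir Directory containing `planeA.tif`, `planeB.tif`,
#'   `sequence.json`.
#' @return A [biplane_sequence()]; ground-truth translations, when present,
#'   are attached as attribute `"truth_translations"`.
#' @export
read_sequence <- function(dir) {
  side_path <- file.path(dir, "sequence.json")
  if (!file.exists(side_path)) stop("no sidecar found: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  rd <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(p) round(p * 65535))
  }
  fa <- rd(file.path(dir, "planeA.tif"))
  fb <- rd(file.path(dir, "planeB.tif"))
  if (length(fa) != length(fb))
    stop(sprintf("frame count mismatch: plane A has %d, plane B has %d",
                 length(fa), length(fb)))
  if (length(side$contrasted) != length(fa)) {
    missing_idx <- setdiff(seq_along(fa), seq_along(side$contrasted))
    stop("missing contrast annotation for frame(s) ",
         paste(missing_idx, collapse = ", "))
  }
  geom <- projection_geometry(matrix(side$geometry$P_A, 3, 4, byrow = TRUE),
                              matrix(side$geometry$P_B, 3, 4, byrow = TRUE),
                              side$geometry$image_shape,
                              side$geometry$pixel_spacing)
  seqc <- biplane_sequence(fa, fb, side$contrasted, side$frame_rate, geom,
                           intensity_range = side$intensity_range)
  if (!is.null(side$truth_translations))
    attr(seqc, "truth_translations") <- matrix(unlist(side$truth_translations),
                                               ncol = 3,
                                               byrow = !is.matrix(side$truth_translations))
  seqc
}

#' Run configuration for the end-to-end pipeline
#'
#' @param measure Similarity measure name (see [similarity_config()]).
#' @param alpha Edge weight for combined measures.
#' @param search A [search_config()].
#' @param preproc_params List overriding [preprocess_plane()] parameters.
#' @param stages Character vector out of `"register"`, `"filter"`,
#'   `"best_frame"`.
#' @param seed Integer seed recorded in the report.
#' @param selector_measure Optional cross-selection measure for best-frame
#'   ranking.
#' @return Object of class `run_config`.
#' @export
run_config <- function(measure = "cade+edge", alpha = 1,
                       search = search_config(),
                       preproc_params = list(),
                       stages = c("register", "filter", "best_frame"),
                       seed = 1L, selector_measure = NULL) {
  structure(list(measure = measure, alpha = alpha, search = search,
                 preproc_params = preproc_params, stages = stages,
                 seed = as.integer(seed), selector_measure = selector_measure),
            class = "run_config")
}

#' Run the registration pipeline on a sequence
#'
#' Registers every contrasted frame, optionally selects the best frame and
#' applies Markov temporal filtering (training the confidence and transition
#' models on the sequence's own unfiltered results unless models are given),
#' and assembles a reproducible report: software version, configuration
#' hash, seed, per-frame estimates, similarity values, filtered trajectory,
#' errors against ground truth when available, and the degenerate-event
#' counters.
#'
#' @param sequence A [biplane_sequence()] or a directory readable by
#'   [read_sequence()].
#' @param model An [atrium_model()] or a model file readable by
#'   [read_model()].
#' @param config A [run_config()].
#' @param truth Optional `ground_truth` (or n x 3 translation matrix).
#' @param confidence,transition Optional pre-trained temporal models.
#' @param out Optional path; when given the report is written as JSON.
#' @return The report, an object of class `la_report` (a list).
#' @export
run_pipeline <- function(sequence, model, config = run_config(), truth = NULL,
                         confidence = NULL, transition = NULL, out = NULL) {
  la_log_reset()
  if (is.character(sequence)) {
    dirseq <- read_sequence(sequence)
    if (is.null(truth) && !is.null(attr(dirseq, "truth_translations")))
      truth <- attr(dirseq, "truth_translations")
    sequence <- dirseq
  }
  if (is.character(model)) model <- read_model(model)
  measure <- similarity_config(config$measure, config$alpha)
  regs <- register_sequence(sequence, model, config$search, measure,
                            preproc_params = config$preproc_params)
  if (!is.null(truth)) regs <- registration_errors(regs, truth)

  report <- list(
    version = as.character(utils::packageVersion("atriareg")),
    seed = config$seed,
    config_hash = config_hash(config),
    measure = measure$measure, alpha = measure$alpha,
    frames = regs
  )

  if ("best_frame" %in% config$stages && nrow(regs) > 0) {
    sel <- select_best_frame(regs, config$selector_measure,
                             sequence = sequence, model = model)
    report$best_frame <- as.integer(sel)
    if (!is.null(truth))
      report$best_frame_error_mm <- regs$error_mm[regs$frame == as.integer(sel)]
  }

  if ("filter" %in% config$stages && nrow(regs) >= 2) {
    if (is.null(confidence)) {
      confidence <- if (!is.null(truth) && length(unique(regs$rho)) >= 2)
        fit_confidence(regs[, c("rho", "error_mm")])
      else structure(list(slope = 0, intercept = 3.2, floor = 0.1),
                     class = "confidence_model")   # interuser-variability scale
    }
    if (is.null(transition)) {
      tr_src <- if (!is.null(truth)) {
        tt <- if (inherits(truth, "ground_truth")) truth$translations else as.matrix(truth)
        list(list(translations = tt, frame_rate = sequence$frame_rate))
      } else {
        list(list(translations = as.matrix(regs[, c("tx", "ty", "tz")]),
                  frame_rate = sequence$frame_rate))
      }
      transition <- fit_transition(tr_src)
    }
    tr <- smooth_trajectory(regs, confidence, transition,
                            frame_rate = sequence$frame_rate)
    report$filtered <- tr$filtered
    if (!is.null(truth)) {
      ev <- evaluate_trajectory(tr$filtered, truth, frames = regs$frame)
      report$filtered_errors_mm <- ev$error_mm
      report$mean_filtered_error_mm <- attr(ev, "mean_error")
      report$mean_unfiltered_error_mm <- mean(regs$error_mm)
    }
  }
  report$log_counters <- as.list(la_log_counters())
  class(report) <- "la_report"
  if (!is.null(out)) write_report(report, out)
  report
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  # tiny stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Write a pipeline report as JSON
#'
#' @param report An `la_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  r <- unclass(report)
  r$frames <- as.data.frame(r$frames)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @export
print.la_report <- function(x, ...) {
  cat(sprintf("<la_report> %s, %d frames, seed %d\n", x$measure, nrow(x$frames), x$seed))
  if (!is.null(x$best_frame)) cat("  best frame:", x$best_frame, "\n")
  if (!is.null(x$mean_filtered_error_mm))
    cat(sprintf("  mean error: %.2f mm unfiltered, %.2f mm filtered\n",
                x$mean_unfiltered_error_mm, x$mean_filtered_error_mm))
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `search` is a nested
#' block with [search_config()] fields.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  search <- do.call(search_config, y$search %||% list())
  run_config(measure = y$measure %||% "cade+edge",
             alpha = y$alpha %||% 1,
             search = search,
             preproc_params = y$preproc_params %||% list(),
             stages = y$stages %||% c("register", "filter", "best_frame"),
             seed = y$seed %||% 1L,
             selector_measure = y$selector_measure)
}
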