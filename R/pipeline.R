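#' Run the full counting-and-quantification pipeline
#'
#' Wires the workflow end to end: detect candidates on every tile, classify
#' them, sum the CART count, invert the calibration curve to a
#' concentration estimate, and flag results against the fit's stored
#' LOD/LOQ ("not detected" below the detection threshold; "detected, below
#' quantification" between LOD and LOQ). A count at or below the fitted
#' blank reports concentration 0 (flagged "not_detected") rather than an
#' error.
#'
#' @param tiles list of [carfind_image] objects/matrices, or a directory
#'   containing TIFF tiles.
#' @param model a `carfind_model` or path to a saved model.
#' @param fit a `calibration_fit` with LOD/LOQ filled (see [lod_loq()]),
#'   or a path to a fit JSON written by [write_fit()].
#' @param config a [prefilter_config].
#' @param sample_id identifier for the report.
#' @param out_dir if non-`NULL`, the report and a run manifest are written
#'   there as JSON.
#' @return object of class `carfind_report`: list with `sample_id`,
#'   `per_class_counts`, `cart_count`, `tiles`, `estimated_concentration`,
#'   `flag` (`"quantified"`, `"detected_below_quantification"`, or
#'   `"not_detected"`), `lod`, `loq`, `fit_form`.
#' @export
run_pipeline <- function(tiles, model, fit, config = prefilter_config(),
                         sample_id = "sample", out_dir = NULL) {
  if (is.character(tiles) && length(tiles) == 1L && dir.exists(tiles)) {
    paths <- sort(list.files(tiles, pattern = "\\.tiff?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(paths) == 0L) stop("no TIFF tiles in ", tiles, call. = FALSE)
    tiles <- lapply(paths, read_image)
  }
  if (is.character(model)) model <- load_model(model)
  if (is.character(fit)) fit <- read_fit(fit)
  if (is.na(fit$lod) || is.na(fit$loq))
    stop("calibration fit has no LOD/LOQ; run lod_loq() first",
         call. = FALSE)
  counts <- count_sample(tiles, model, config, sample_id = sample_id)
  y <- counts$cart_count
  y_d <- fit$blank_mean +
    2 * stats::qnorm(fit$confidence) *
    (if (fit$blank_sd == 0) fit$residual_sd else fit$blank_sd)
  y_q <- fit$blank_mean +
    10 * (if (fit$blank_sd == 0) fit$residual_sd else fit$blank_sd)
  conc <- if (y <= fit$blank_mean || (fit$form == "power" && y <= 0)) 0
          else invert_fit(fit, y)
  flag <- if (y < y_d) "not_detected"
          else if (y < y_q) "detected_below_quantification"
          else "quantified"
  report <- structure(list(sample_id = sample_id,
                           tiles = counts$tiles,
                           per_class_counts = counts$per_class_counts,
                           cart_count = y,
                           estimated_concentration = conc,
                           flag = flag,
                           lod = fit$lod, loq = fit$loq,
                           fit_form = fit$form),
                      class = "carfind_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(schema_version = 1L, report = unclass(report)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      run_manifest(config, n_tiles = counts$tiles,
                   per_stage = list(cart_count = y,
                                    total_candidates =
                                      sum(counts$per_class_counts))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.carfind_report <- function(x, ...) {
  cat(sprintf("<carfind_report> %s: CART count %d over %d tiles\n",
              x$sample_id, x$cart_count, x$tiles))
  cat(sprintf("  estimated concentration %.4g cells/uL [%s]\n",
              x$estimated_concentration, x$flag))
  cat(sprintf("  LOD %.3g, LOQ %.3g cells/uL (%s fit)\n",
              x$lod, x$loq, x$fit_form))
  invisible(x)
}

## Reproducibility manifest for a pipeline run.
run_manifest <- function(config, n_tiles, per_stage = list()) {
  list(tool = "carfind",
       version = as.character(utils::packageVersion("carfind")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       n_tiles = n_tiles,
       config = unclass(config),
       per_stage = per_stage)
}

#' Write and read a calibration fit as JSON
#'
#' The JSON carries the model form, parameters, goodness of fit, blank
#' statistics, LOD/LOQ, confidence level and fitting scale.
#'
#' @param fit a `calibration_fit`.
#' @param path JSON path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  x <- unclass(fit)
  x$data <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("form", "a", "b")
  if (!all(need %in% names(x)))
    stop("not a calibration fit file: ", path, call. = FALSE)
  x$data <- NULL
  fit <- new_calibration_fit(x$form, x$a, x$b, x$r_squared, x$residual_sd,
                             x$n, data = NULL, scale = x$scale)
  for (f in c("blank_mean", "blank_sd", "lod", "loq", "confidence"))
    if (!is.null(x[[f]])) fit[[f]] <- x[[f]]
  fit
}
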