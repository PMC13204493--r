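#' carfind: label-free brightfield counting of surface-captured CAR T-cells
#'
#' End-to-end image-analysis chain for digital CAR T-cell counting on a
#' CD19-functionalized microfluidic sensor: candidate detection by a
#' five-stage prefilter, four-category random-forest classification,
#' concentration calibration (power and logarithmic fits) with blank-based
#' 95% LOD/LOQ, fluorescence-validation statistics, and a ground-truthed
#' synthetic data generator.
#'
#' Coordinate convention used throughout: images are matrices indexed
#' `[row, col]`, 1-based, origin at the top-left pixel. Detection tables use
#' `x_px = col`, `y_px = row`. Intensities are 16-bit (0--65535) on disk and
#' real-valued in memory.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a brightfield image object
#'
#' Thin container pairing a matrix of intensities with the physical pixel
#' size at the sample plane. The default pixel size corresponds to a 6.5 um
#' camera pixel behind a 40x objective (6.5 / 40 = 0.1625 um).
#'
#' @param pixels numeric matrix of non-negative intensities (16-bit range).
#' @param pixel_size_um physical size of one pixel at the sample plane (um).
#' @param name identifier string.
#' @return An object of class `carfind_image`: a list with elements
#'   `pixels`, `pixel_size_um`, `name`.
#' @export
carfind_image <- function(pixels, pixel_size_um = 0.1625, name = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 65535))
    stop("stored intensities must lie in [0, 65535]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 name = as.character(name)[1L]),
            class = "carfind_image")
}

#' @export
print.carfind_image <- function(x, ...) {
  cat(sprintf("<carfind_image> %s: %d x %d px, %.4f um/px, range [%g, %g]\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

## Accept either a carfind_image or a bare matrix everywhere downstream.
as_pixels <- function(image) {
  if (inherits(image, "carfind_image")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else stop("expected a carfind_image or a numeric matrix", call. = FALSE)
}

#' Read a single-plane grayscale image
#'
#' Reads 16-bit monochrome TIFF (the acquisition format) or, for fixtures,
#' grayscale PNG. Intensities are preserved bit-exactly; the sample-plane
#' pixel size comes from the argument (configuration), never from file
#' metadata.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um sample-plane pixel size to attach (um).
#' @param name identifier; defaults to the file name.
#' @return A [carfind_image].
#' @export
read_image <- function(path, pixel_size_um = 0.1625, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path)
    if (is.matrix(px)) px <- round(px * 65535)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(px)) != 2L)
    stop(sprintf(
      "expected a single-plane grayscale image, got array of shape (%s)",
      paste(dim(px), collapse = ", ")), call. = FALSE)
  carfind_image(px * 1.0, pixel_size_um = pixel_size_um, name = name)
}

#' Write a 16-bit grayscale TIFF
#'
#' Intensities are rounded to integers and must lie in the 16-bit range;
#' the write/read round trip is bit-exact.
#'
#' @param image a [carfind_image] or numeric matrix.
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- round(as_pixels(image))
  if (any(px < 0) || any(px > 65535))
    stop("intensities outside 16-bit range; rescale first", call. = FALSE)
  ok <- tryCatch(tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L),
                 error = function(e) stop("cannot write image: ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write a real-valued filter response as a rescaled TIFF
#'
#' Intermediate prefilter responses are real-valued; for inspection they are
#' affinely mapped onto the 16-bit range and written as TIFF, with a sidecar
#' JSON (`<path>.json`) recording the slope and offset so the mapping is
#' invertible.
#'
#' @param response numeric matrix.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_response <- function(response, path) {
  stopifnot(is.matrix(response), is.numeric(response))
  lo <- min(response); hi <- max(response)
  slope <- if (hi > lo) 65535 / (hi - lo) else 0
  scaled <- (response - lo) * slope
  write_image(scaled, path)
  jsonlite::write_json(
    list(offset = lo, slope = slope,
         note = "stored = (value - offset) * slope"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read detection tables
#'
#' Detections are stored as CSV with header
#' `image, x_px, y_px, radius_px, class, score` (`x_px` = column,
#' `y_px` = row, 1-based). Unlabeled candidates carry class
#' `"unclassified"`.
#'
#' @param candidates list of candidates as produced by [detect_candidates()],
#'   or a data frame with the columns above.
#' @param path output CSV path.
#' @param image image identifier recorded in the first column when
#'   `candidates` is a candidate list.
#' @return `path` invisibly for the writer; a data frame for the reader.
#' @export
write_detections <- function(candidates, path, image = "") {
  df <- if (is.data.frame(candidates)) candidates else
    detections_frame(candidates, image = image)
  need <- c("image", "x_px", "y_px", "radius_px", "class", "score")
  if (!all(need %in% names(df)))
    stop("detections need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ok <- tryCatch(utils::write.csv(df[, need], path, row.names = FALSE),
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.csv(path, colClasses = c(
    image = "character", x_px = "numeric", y_px = "numeric",
    radius_px = "numeric", class = "character", score = "numeric"))
}

#' Flatten a candidate list to a detection data frame
#'
#' @inheritParams write_detections
#' @return data frame with columns image, x_px, y_px, radius_px, class, score.
#' @export
detections_frame <- function(candidates, image = "") {
  if (length(candidates) == 0L)
    return(data.frame(image = character(), x_px = numeric(),
                      y_px = numeric(), radius_px = numeric(),
                      class = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(
    image = image,
    x_px = vapply(candidates, function(c) c$center[2L], 0),
    y_px = vapply(candidates, function(c) c$center[1L], 0),
    radius_px = vapply(candidates, function(c) c$radius_px, 0),
    class = vapply(candidates, function(c)
      if (is.null(c$label)) "unclassified" else as.character(c$label), ""),
    score = vapply(candidates, function(c) c$peak_score, 0),
    stringsAsFactors = FALSE)
}

#' Read and write region-of-interest sets
#'
#' ROI sets pair brightfield detections with fluorescence images sharing the
#' same stage coordinates. CSV schema: `image, x_px, y_px, radius_px, label`.
#'
#' @param rois data frame with the columns above.
#' @param path CSV path.
#' @export
write_rois <- function(rois, path) {
  need <- c("image", "x_px", "y_px", "radius_px", "label")
  if (!all(need %in% names(rois)))
    stop("ROI set needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  utils::write.csv(rois[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  utils::read.csv(path, colClasses = c(
    image = "character", x_px = "numeric", y_px = "numeric",
    radius_px = "numeric", label = "character"))
}

#' Imaging geometry of the acquisition system
#'
#' Defaults reflect the instrument: 6.5 um camera pixel, 40x objective,
#' 2048 x 2048 view, 30 tiles covering the channel per scan. The
#' sample-plane pixel is `camera_pixel_um / magnification`.
#'
#' @param camera_pixel_um camera pixel pitch (um).
#' @param magnification objective magnification (dimensionless).
#' @param view_px image size as (height, width) in pixels.
#' @param images_per_set number of tiles per channel scan.
#' @return list with the fields above plus `sample_pixel_um`.
#' @export
imaging_geometry <- function(camera_pixel_um = 6.5, magnification = 40,
                             view_px = c(2048L, 2048L),
                             images_per_set = 30L) {
  stopifnot(camera_pixel_um > 0, magnification > 0, all(view_px > 0),
            images_per_set > 0)
  list(camera_pixel_um = camera_pixel_um, magnification = magnification,
       view_px = as.integer(view_px), images_per_set = as.integer(images_per_set),
       sample_pixel_um = camera_pixel_um / magnification)
}

#' Microfluidic channel volume
#'
#' Rectangular-prism volume of the linear capture channel, reported in
#' microliters to 2 significant figures (1 mm^3 = 1 uL).
#'
#' @param height_um channel height in micrometers.
#' @param width_mm channel width in millimeters.
#' @param length_mm channel length in millimeters.
#' @return volume in uL, rounded to 2 significant figures.
#' @examples
#' channel_volume(203, 1.0, 35)  # 7.1 uL
#' @export
channel_volume <- function(height_um, width_mm, length_mm) {
  if (any(c(height_um, width_mm, length_mm) <= 0))
    stop("all channel dimensions must be positive", call. = FALSE)
  signif((height_um * 1e-3) * width_mm * length_mm, 2)
}

#' Default configuration
#'
#' Returns the full default configuration as a nested list; every numeric
#' default used by the pipeline appears here. Use [write_config()] /
#' [read_config()] for the JSON form.
#'
#' @return nested list of configuration blocks.
#' @export
default_config <- function() {
  list(
    geometry = imaging_geometry(),
    pixel_size_um = 0.1625,
    prefilter = unclass(prefilter_config()),
    objects = list(n_trees = 100L, seed = 20240101L),
    fluor = list(sd_floor = 1e-4, em_max_iter = 500L, em_tol = 1e-8),
    scene = unclass(scene_config()),
    calibration = unclass(cal_sim_config()),
    lod = list(confidence = 0.95, z = stats::qnorm(0.95),
               loq_sd_multiple = 10)
  )
}

#' @rdname default_config
#' @param config configuration list.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
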