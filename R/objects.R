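#' Object categories
#'
#' The four object categories encountered on the sensor surface after
#' washing: CAR T-cells, platelets, residual red blood cells, and
#' debris/anomalous/broken cells ("OTHER").
#'
#' @return character vector of the four class names, in canonical order.
#' @export
object_classes <- function() c("CART", "PLATELET", "RBC", "OTHER")

#' Feature names, in the frozen order
#'
#' The per-object feature contract: 16 real-valued features covering shape
#' (area, equivalent radius, perimeter, circularity, eccentricity),
#' intensity statistics over the mask (mean, median, SD, min, max, three
#' quartiles), ring contrast (mean outer-annulus minus mean inner-disc
#' intensity), the mean stage-1 texture response over the mask, and the
#' match-filter peak score. The ordering is fixed so trained models are
#' portable.
#'
#' @return character vector of feature names.
#' @export
feature_names <- function() {
  c("area_px", "equivalent_radius_px", "perimeter_px", "circularity",
    "eccentricity", "mean_intensity", "median_intensity", "sd_intensity",
    "min_intensity", "max_intensity", "q25_intensity", "q50_intensity",
    "q75_intensity", "ring_contrast", "local_sd_mean", "peak_score")
}

#' Extract the feature vector of a candidate
#'
#' Intensity statistics are computed over the mask pixels of the raw crop;
#' the perimeter is estimated from the count of 4-connected mask/background
#' edges scaled by pi/4 (so a digital disc has circularity ~1); eccentricity
#' comes from the second moments of the mask; ring contrast compares the
#' mean intensity in an annulus (1 to 1.5 equivalent radii from the mask
#' centroid) against the inner disc (0.6 equivalent radii), capturing the
#' dark-rim/bright-center appearance of defocused cells.
#'
#' @param candidate a candidate from [radial_segment()] /
#'   [detect_candidates()] (needs `crop`, `mask`, `bbox`, `peak_score`).
#' @param std_response the stage-1 [local_std_filter()] response of the
#'   full tile (matrix), or `NULL` to set `local_sd_mean` from the crop's
#'   own response.
#' @return named numeric vector in [feature_names()] order.
#' @export
extract_features <- function(candidate, std_response = NULL) {
  mask <- candidate$mask
  crop <- candidate$crop
  if (is.null(mask) || sum(mask) == 0L)
    stop("candidate has an empty mask", call. = FALSE)
  area <- sum(mask)
  req <- sqrt(area / pi)
  perim <- mask_perimeter(mask)
  circ <- 4 * pi * area / perim^2
  ecc <- mask_eccentricity(mask)
  vals <- crop[mask]
  qs <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sdp <- sqrt(mean((vals - mean(vals))^2))  # population SD

  ## ring contrast around the mask centroid
  idx <- which(mask, arr.ind = TRUE)
  cr <- mean(idx[, 1L]); cc <- mean(idx[, 2L])
  rho <- sqrt(outer((seq_len(nrow(crop)) - cr)^2,
                    (seq_len(ncol(crop)) - cc)^2, `+`))
  inner <- rho <= 0.6 * req
  annulus <- rho > req & rho <= 1.5 * req
  ring_contrast <- if (any(annulus) && any(inner))
    mean(crop[annulus]) - mean(crop[inner]) else 0

  local_sd_mean <- if (!is.null(std_response)) {
    rr <- candidate$bbox[["row"]] + idx[, 1L] - 1L
    cc2 <- candidate$bbox[["col"]] + idx[, 2L] - 1L
    mean(std_response[cbind(rr, cc2)])
  } else {
    sr <- local_std_filter(crop, min(9L, oddify(min(dim(crop)))))
    mean(sr[mask])
  }

  out <- c(area, req, perim, circ, ecc,
           mean(vals), stats::median(vals), sdp, min(vals), max(vals),
           qs[1L], qs[2L], qs[3L],
           ring_contrast, local_sd_mean, candidate$peak_score)
  names(out) <- feature_names()
  out
}

oddify <- function(n) if (n %% 2L == 0L) n - 1L else n

## Perimeter estimate: 4-connected boundary edge count times 0.76, an
## empirical Manhattan-to-Euclidean correction calibrated on digital discs
## (edge count ~ 8.1-8.8 r over the radii seen here), keeping disc
## circularity within a few percent of 1.
mask_perimeter <- function(mask) {
  m <- mask * 1L
  pad <- rbind(0L, cbind(0L, m, 0L), 0L)
  n1 <- nrow(pad); n2 <- ncol(pad)
  edges <- sum(pad[-1L, ] != pad[-n1, ]) + sum(pad[, -1L] != pad[, -n2])
  edges * 0.76
}

## Eccentricity from the covariance of mask pixel coordinates.
mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(0)
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0) return(0)
  sqrt(max(0, 1 - ev[2L] / ev[1L]))
}

#' Build a feature matrix for a list of candidates
#'
#' @param candidates list of candidates with `features` filled (as returned
#'   by [detect_candidates()]), or without, in which case features are
#'   computed from crops.
#' @param std_response optional full-tile stage-1 response.
#' @return numeric matrix, one row per candidate, columns [feature_names()].
#' @export
features_matrix <- function(candidates, std_response = NULL) {
  if (length(candidates) == 0L)
    return(matrix(numeric(0), 0L, length(feature_names()),
                  dimnames = list(NULL, feature_names())))
  rows <- lapply(candidates, function(cd) {
    if (!is.null(cd$features)) cd$features
    else extract_features(cd, std_response)
  })
  do.call(rbind, rows)
}

#' Train the object classifier
#'
#' Fits a 100-tree random forest (unlimited depth, `sqrt(p)` features per
#' split, bootstrap resampling) on labeled feature vectors. Training is
#' deterministic given the seed.
#'
#' @param features numeric matrix (rows = objects, columns in
#'   [feature_names()] order) or data frame.
#' @param labels character or factor vector of classes from
#'   [object_classes()].
#' @param n_trees number of trees (default 100).
#' @param seed RNG seed for reproducible fitting.
#' @return object of class `carfind_model`: list with `forest`,
#'   `feature_order`, `classes`, `n_trees`, `seed`, `oob_error`, `version`.
#' @export
train_classifier <- function(features, labels, n_trees = 100L,
                             seed = 20240101L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    stop("one label per feature row required", call. = FALSE)
  present <- unique(labels)
  if (length(present) < 2L)
    stop("training requires at least 2 classes", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 5L))
    stop("every class needs at least 5 examples; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "), call. = FALSE)
  bad <- setdiff(present, object_classes())
  if (length(bad))
    stop("unknown classes: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(colnames(features))) colnames(features) <- feature_names()
  y <- factor(labels, levels = object_classes())
  y <- droplevels(y)
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = as.data.frame(features), y = y, ntree = n_trees,
    mtry = max(1L, floor(sqrt(ncol(features)))))
  structure(list(forest = forest,
                 feature_order = colnames(features),
                 classes = levels(y),
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 oob_error = mean(forest$err.rate[n_trees, "OOB"]),
                 version = 1L),
            class = "carfind_model")
}

#' @export
print.carfind_model <- function(x, ...) {
  cat(sprintf("<carfind_model> %d-tree random forest over %d features; OOB error %.3f\n",
              x$n_trees, length(x$feature_order), x$oob_error))
  invisible(x)
}

#' Predict classes for a feature matrix
#'
#' @param object a `carfind_model`.
#' @param newdata feature matrix or data frame with the model's feature
#'   columns.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.carfind_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(as.matrix(newdata))
  if (ncol(newdata) != length(object$feature_order))
    stop(sprintf("feature length mismatch: model expects %d, got %d",
                 length(object$feature_order), ncol(newdata)),
         call. = FALSE)
  colnames(newdata) <- object$feature_order
  ## the forest may come from a serialized file, so make sure the
  ## randomForest S3 predict method is registered before dispatch
  requireNamespace("randomForest", quietly = TRUE)
  ## aggregate votes and take a deterministic argmax (first level wins on
  ## ties) so reloaded models reproduce predictions exactly
  votes <- stats::predict(object$forest, newdata, type = "prob")
  cls <- colnames(votes)[max.col(votes, ties.method = "first")]
  factor(cls, levels = object$classes)
}

#' Classify detected candidates
#'
#' Labels every candidate and tallies counts per category. Counts always
#' sum to the number of candidates.
#'
#' @param model a `carfind_model`.
#' @param candidates list of candidates with features
#'   (from [detect_candidates()]).
#' @return list with `candidates` (labels filled) and `counts`
#'   (named integer vector over [object_classes()]).
#' @export
classify <- function(model, candidates) {
  counts <- stats::setNames(integer(length(object_classes())),
                            object_classes())
  if (length(candidates) == 0L)
    return(list(candidates = candidates, counts = counts))
  fm <- features_matrix(candidates)
  pred <- as.character(predict(model, fm))
  for (i in seq_along(candidates)) candidates[[i]]$label <- pred[i]
  tab <- table(factor(pred, levels = object_classes()))
  counts[names(tab)] <- as.integer(tab)
  list(candidates = candidates, counts = counts)
}

#' Evaluate a classifier on a labeled test set
#'
#' Builds the 4 x 4 confusion matrix and reports one-vs-rest sensitivity
#' (TP / (TP + FN)) and specificity (TN / (TN + FP)) for each class, plus
#' overall accuracy.
#'
#' @param model a `carfind_model`.
#' @param features test feature matrix.
#' @param labels true classes.
#' @param positive class reported as the headline operating point
#'   (default `"CART"`).
#' @return object of class `carfind_eval`: list with `confusion`
#'   (truth rows x prediction columns), `sensitivity`, `specificity`
#'   (named per class), `accuracy`, `n_test`, `positive`.
#' @export
evaluate_classifier <- function(model, features, labels, positive = "CART") {
  pred <- as.character(predict(model, features))
  eval_report(as.character(labels), pred, positive = positive)
}

#' Confusion-matrix report from true and predicted labels
#'
#' @param truth,pred character vectors of true and predicted classes.
#' @param positive headline class.
#' @return a `carfind_eval` (see [evaluate_classifier()]).
#' @export
eval_report <- function(truth, pred, positive = "CART") {
  if (length(truth) == 0L) stop("empty test set", call. = FALSE)
  lv <- object_classes()
  cm <- table(truth = factor(truth, levels = lv),
              pred = factor(pred, levels = lv))
  sens <- spec <- stats::setNames(numeric(length(lv)), lv)
  for (cl in lv) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- sum(cm) - tp - fn - fp
    sens[cl] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[cl] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  structure(list(confusion = unclass(cm),
                 sensitivity = sens, specificity = spec,
                 accuracy = sum(diag(cm)) / sum(cm),
                 n_test = length(truth), positive = positive),
            class = "carfind_eval")
}

#' @export
print.carfind_eval <- function(x, ...) {
  cat(sprintf("<carfind_eval> n = %d, accuracy %.3f\n", x$n_test, x$accuracy))
  cat(sprintf("  %s: sensitivity %.3f, specificity %.3f\n", x$positive,
              x$sensitivity[x$positive], x$specificity[x$positive]))
  print(x$confusion)
  invisible(x)
}

#' Save and load a trained model
#'
#' Models are serialized with an embedded feature-order manifest and a
#' format version; a reloaded model yields identical predictions.
#'
#' @param model a `carfind_model`.
#' @param path file path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "carfind_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "carfind_model") || is.null(model$feature_order))
    stop("not a carfind model file: ", path, call. = FALSE)
  model
}
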