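#' Count CAR T-cells across the tiles of one sample
#'
#' Runs detection and classification on every tile and sums the
#' CART-labeled objects. Tiles are treated as disjoint fields of view (no
#' cross-tile deduplication); per-tile provenance is retained.
#'
#' @param tiles list of [carfind_image] objects or matrices.
#' @param model a `carfind_model`.
#' @param config a [prefilter_config].
#' @param sample_id identifier recorded in the result.
#' @param spiked_concentration known spiked concentration (cells/uL) or
#'   `NA` for unknowns.
#' @return object of class `carfind_counts`: list with `sample_id`,
#'   `tiles` (number analyzed), `per_class_counts`, `cart_count`,
#'   `per_tile` (data frame of per-tile class counts),
#'   `spiked_concentration`.
#' @export
count_sample <- function(tiles, model, config = prefilter_config(),
                         sample_id = "sample",
                         spiked_concentration = NA_real_) {
  if (length(tiles) == 0L) stop("need at least one tile", call. = FALSE)
  per_tile <- matrix(0L, length(tiles), length(object_classes()),
                     dimnames = list(NULL, object_classes()))
  for (i in seq_along(tiles)) {
    cands <- detect_candidates(tiles[[i]], config)
    per_tile[i, ] <- classify(model, cands)$counts
  }
  totals <- colSums(per_tile)
  structure(list(sample_id = sample_id,
                 tiles = length(tiles),
                 per_class_counts = totals,
                 cart_count = unname(totals["CART"]),
                 per_tile = as.data.frame(per_tile),
                 spiked_concentration = spiked_concentration),
            class = "carfind_counts")
}

#' @export
print.carfind_counts <- function(x, ...) {
  cat(sprintf("<carfind_counts> %s: %d tiles, CART count %d\n",
              x$sample_id, x$tiles, x$cart_count))
  print(x$per_class_counts)
  invisible(x)
}

new_calibration_fit <- function(form, a, b, r_squared, residual_sd,
                                n, data, scale) {
  structure(list(form = form, a = a, b = b, r_squared = r_squared,
                 residual_sd = residual_sd, n = n, data = data,
                 scale = scale,
                 blank_mean = NA_real_, blank_sd = NA_real_,
                 lod = NA_real_, loq = NA_real_, confidence = NA_real_),
            class = "calibration_fit")
}

#' Fit a power-law calibration curve (buffer samples)
#'
#' Least-squares fit of `count = a * concentration^b` by log-log linear
#' regression (`ln y = ln a + b ln x`). R-squared and the residual SD are
#' reported on the log-log fitting scale.
#'
#' @param concentrations spiked concentrations (cells/uL), all positive,
#'   at least 3 distinct values.
#' @param counts observed cell counts, all positive (the power form is
#'   undefined at zero).
#' @return object of class `calibration_fit` with `form = "power"`,
#'   parameters `a` (> 0) and `b`, `r_squared`, `residual_sd`.
#' @export
fit_power <- function(concentrations, counts) {
  check_cal_input(concentrations, counts)
  if (any(counts <= 0))
    stop("power fit requires positive counts (form is undefined at 0)",
         call. = FALSE)
  lx <- log(concentrations); ly <- log(counts)
  fit <- stats::lm(ly ~ lx)
  co <- stats::coef(fit)
  new_calibration_fit(
    form = "power", a = exp(unname(co[1L])), b = unname(co[2L]),
    r_squared = r_squared_of(ly, stats::fitted(fit)),
    residual_sd = stats::sd(stats::residuals(fit)),
    n = length(counts),
    data = data.frame(concentration = concentrations, count = counts),
    scale = "log-log")
}

#' Fit a logarithmic calibration curve (whole-blood samples)
#'
#' Ordinary least squares of `count = a * ln(concentration) + b`; suited to
#' whole blood, where a high blank background gives a nonzero intercept.
#' The blank enters only through [lod_loq()], never by subtraction from the
#' curve. R-squared is reported on the semilog fitting scale.
#'
#' @inheritParams fit_power
#' @return a `calibration_fit` with `form = "log"`, slope `a` and
#'   intercept `b`.
#' @export
fit_log <- function(concentrations, counts) {
  check_cal_input(concentrations, counts,
                  zero_hint = "use the blank separately via lod_loq()")
  lx <- log(concentrations)
  fit <- stats::lm(counts ~ lx)
  co <- stats::coef(fit)
  new_calibration_fit(
    form = "log", a = unname(co[2L]), b = unname(co[1L]),
    r_squared = r_squared_of(counts, stats::fitted(fit)),
    residual_sd = stats::sd(stats::residuals(fit)),
    n = length(counts),
    data = data.frame(concentration = concentrations, count = counts),
    scale = "count vs log(concentration)")
}

check_cal_input <- function(concentrations, counts, zero_hint = NULL) {
  if (length(concentrations) != length(counts))
    stop("concentrations and counts must have equal length", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be positive",
         if (!is.null(zero_hint)) paste0("; ", zero_hint), call. = FALSE)
  if (length(unique(concentrations)) < 3L)
    stop("need at least 3 distinct concentrations", call. = FALSE)
}

## R^2 on the fitting scale; a flat response is reported as 0.
r_squared_of <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Predicted counts from a calibration fit
#'
#' @param object a `calibration_fit`.
#' @param concentration concentrations (cells/uL), positive.
#' @param ... unused.
#' @return predicted counts on the original count scale.
#' @export
predict.calibration_fit <- function(object, concentration, ...) {
  stopifnot(all(concentration > 0))
  switch(object$form,
         power = object$a * concentration^object$b,
         log = object$a * log(concentration) + object$b)
}

#' Invert a calibration fit: concentration from a count
#'
#' Closed-form inversion: `x = (y / a)^(1 / b)` for the power form,
#' `x = exp((y - b) / a)` for the logarithmic form.
#'
#' @param fit a `calibration_fit`.
#' @param count observed count(s).
#' @return concentration(s) in cells/uL.
#' @export
invert_fit <- function(fit, count) {
  switch(fit$form,
         power = {
           if (any(count <= 0))
             stop("power curve cannot be inverted at counts <= 0",
                  call. = FALSE)
           (count / fit$a)^(1 / fit$b)
         },
         log = exp((count - fit$b) / fit$a))
}

#' @export
coef.calibration_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
print.calibration_fit <- function(x, ...) {
  eqn <- switch(x$form,
                power = sprintf("count = %.4g * conc^%.4g", x$a, x$b),
                log = sprintf("count = %.4g * ln(conc) + %.4g", x$a, x$b))
  cat(sprintf("<calibration_fit> %s fit: %s\n", x$form, eqn))
  cat(sprintf("  R^2 = %.4f (%s scale), residual SD %.4g, n = %d\n",
              x$r_squared, x$scale, x$residual_sd, x$n))
  if (!is.na(x$lod))
    cat(sprintf("  LOD %.3g, LOQ %.3g cells/uL (%.0f%% certainty; blank %.3g +/- %.3g)\n",
                x$lod, x$loq, 100 * x$confidence, x$blank_mean, x$blank_sd))
  invisible(x)
}

#' 95%-certainty limits of detection and quantification
#'
#' Blank-based decision thresholds on the count scale:
#' `y_D = blank_mean + 2 * z * blank_sd` with `z = qnorm(confidence)`
#' (detection with false-positive and false-negative rates both
#' 1 - confidence; `2 * 1.645 = 3.29` at 95%) and
#' `y_Q = blank_mean + 10 * blank_sd` (quantification). The LOD and LOQ are
#' the concentrations at which the fitted curve equals these thresholds,
#' solved in closed form through [invert_fit()]. If `blank_sd` is 0, the
#' fit's residual SD is substituted.
#'
#' @param fit a `calibration_fit`.
#' @param blank_mean,blank_sd mean and SD of counts from non-spiked
#'   replicates.
#' @param confidence one-sided certainty level (default 0.95).
#' @return the `calibration_fit` with `blank_mean`, `blank_sd`, `lod`,
#'   `loq`, `confidence` filled. Extract with `$lod`, `$loq`.
#' @export
lod_loq <- function(fit, blank_mean, blank_sd, confidence = 0.95) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (blank_sd < 0) stop("`blank_sd` must be >= 0", call. = FALSE)
  sd_eff <- if (blank_sd == 0) fit$residual_sd else blank_sd
  if (is.na(sd_eff)) sd_eff <- 0
  z <- stats::qnorm(confidence)
  y_d <- blank_mean + 2 * z * sd_eff
  y_q <- blank_mean + 10 * sd_eff
  if (fit$form == "power" && (y_d <= 0 || y_q <= 0))
    stop("decision threshold at or below the power curve's infimum (0); ",
         "no finite LOD/LOQ exists", call. = FALSE)
  fit$blank_mean <- blank_mean
  fit$blank_sd <- blank_sd
  fit$confidence <- confidence
  fit$lod <- invert_fit(fit, y_d)
  fit$loq <- invert_fit(fit, y_q)
  fit
}

#' Before/after count ratio with replicate spread
#'
#' Per-replicate ratios of paired counts (e.g. filtration efficiency
#' WBC_after / WBC_before, or attachment retention after/before flushing),
#' with their mean, SD and standard error across replicates.
#'
#' @param before,after paired replicate counts; every `before` must be
#'   positive.
#' @return list of class `ratio_stat`: `ratios`, `ratio` (mean), `sd`,
#'   `se`, `n`, `numerator_count`, `denominator_count` (sums).
#' @export
ratio_stat <- function(before, after) {
  if (length(before) != length(after))
    stop("`before` and `after` must be paired (equal length)", call. = FALSE)
  if (any(before <= 0)) stop("zero or negative denominator count",
                             call. = FALSE)
  ratios <- after / before
  structure(list(ratios = ratios,
                 ratio = mean(ratios),
                 sd = if (length(ratios) > 1L) stats::sd(ratios) else 0,
                 se = if (length(ratios) > 1L)
                   stats::sd(ratios) / sqrt(length(ratios)) else 0,
                 n = length(ratios),
                 numerator_count = sum(after),
                 denominator_count = sum(before)),
            class = "ratio_stat")
}

#' @export
print.ratio_stat <- function(x, ...) {
  cat(sprintf("<ratio_stat> mean ratio %.4g +/- %.3g (SD, n = %d)\n",
              x$ratio, x$sd, x$n))
  invisible(x)
}
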