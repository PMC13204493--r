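#' Per-cell normalized fluorescence statistic
#'
#' Population standard deviation of the ROI pixels divided by their median.
#' The division normalizes across experiments and slight background
#' brightness variations: the statistic is invariant under a multiplicative
#' gain. Clustered receptor signal (bright puncta) raises the SD at a fixed
#' median, so CAR-positive cells score high.
#'
#' @param pixels numeric vector of fluorescence intensities within a cell
#'   ROI (at least 2 values).
#' @return list with `raw_sd` (population SD), `raw_median`, and `stat`
#'   (= raw_sd / raw_median).
#' @export
fluor_statistic <- function(pixels) {
  if (length(pixels) < 2L)
    stop("need at least 2 pixels in the ROI", call. = FALSE)
  med <- stats::median(pixels)
  if (med <= 0)
    stop("zero median: background-dominated ROI", call. = FALSE)
  s <- sqrt(mean((pixels - mean(pixels))^2))
  list(raw_sd = s, raw_median = med, stat = s / med)
}

#' Pair brightfield detections with a fluorescence image
#'
#' For each brightfield ROI (shared stage coordinates), computes the
#' normalized fluorescence statistic over the ROI disc on the fluorescence
#' image. ROIs extending outside the image are skipped with a warning,
#' never silently.
#'
#' @param rois data frame with columns `x_px`, `y_px`, `radius_px`
#'   (1-based pixel coordinates; `x` = column, `y` = row) and optionally
#'   `image`/`label`; e.g. from [read_rois()] or [detections_frame()].
#' @param fluor_image the fluorescence tile ([carfind_image] or matrix).
#' @return data frame with one row per retained ROI: `cell_id`, `x_px`,
#'   `y_px`, `raw_sd`, `raw_median`, `stat`.
#' @export
pair_rois <- function(rois, fluor_image) {
  x <- as_pixels(fluor_image)
  n1 <- nrow(x); n2 <- ncol(x)
  out <- vector("list", nrow(rois))
  skipped <- 0L
  for (i in seq_len(nrow(rois))) {
    r0 <- rois$y_px[i]; c0 <- rois$x_px[i]; rad <- rois$radius_px[i]
    if (r0 - rad < 1 || r0 + rad > n1 || c0 - rad < 1 || c0 + rad > n2) {
      skipped <- skipped + 1L
      next
    }
    rr <- floor(r0 - rad):ceiling(r0 + rad)
    cc <- floor(c0 - rad):ceiling(c0 + rad)
    rho <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    px <- x[rr, cc, drop = FALSE][rho <= rad]
    fs <- fluor_statistic(px)
    out[[i]] <- data.frame(cell_id = i, x_px = c0, y_px = r0,
                           raw_sd = fs$raw_sd, raw_median = fs$raw_median,
                           stat = fs$stat)
  }
  if (skipped > 0L)
    warning(sprintf("%d ROI(s) outside the fluorescence image were skipped",
                    skipped), call. = FALSE)
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(cell_id = integer(), x_px = numeric(),
                      y_px = numeric(), raw_sd = numeric(),
                      raw_median = numeric(), stat = numeric()))
  do.call(rbind, out)
}

#' Two-Gaussian mixture fit with intersection threshold
#'
#' Fits a two-component Gaussian mixture to the per-cell fluorescence
#' statistics by expectation-maximization (k-means initialization),
#' separating the CAR-expressing from the non-expressing population. The
#' gating threshold is the intersection of the two weighted component
#' densities between the means. Components are ordered by ascending mean.
#'
#' @param stats numeric vector of per-cell statistics (>= 20 values).
#' @param seed RNG seed for the k-means initialization.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param sd_floor components whose SD falls below this floor abort the
#'   fit with an error (degenerate spike).
#' @return object of class `mixture_fit`: `weights`, `means`, `sds`
#'   (each length 2, means ascending), `threshold`, `loglik` (trace),
#'   `iterations`.
#' @export
fit_two_gaussians <- function(stats, seed = 20240101L, max_iter = 500L,
                              tol = 1e-8, sd_floor = 1e-4) {
  if (length(stats) < 20L)
    stop("need at least 20 values to fit a two-component mixture",
         call. = FALSE)
  if (length(unique(stats)) < 2L)
    stop("degenerate input: all values identical; no two-component ",
         "structure to fit", call. = FALSE)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(stats, centers = 2L, nstart = 5L))
  mu <- as.numeric(km$centers)
  if (abs(diff(mu)) < sd_floor)
    stop("degenerate input: cluster means coincide; no two-component ",
         "structure to fit", call. = FALSE)
  w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(stats)
  sg <- vapply(1:2, function(k) {
    v <- stats[km$cluster == k]
    s <- if (length(v) > 1L) stats::sd(v) else 0
    max(s, sd_floor * 10)
  }, 0)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(stats, mu[1L], sg[1L])
    d2 <- w[2L] * stats::dnorm(stats, mu[2L], sg[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    g1 <- d1 / tot
    g2 <- 1 - g1
    n1 <- sum(g1); n2 <- sum(g2)
    w <- c(n1, n2) / length(stats)
    mu <- c(sum(g1 * stats) / n1, sum(g2 * stats) / n2)
    sg <- sqrt(c(sum(g1 * (stats - mu[1L])^2) / n1,
                 sum(g2 * (stats - mu[2L])^2) / n2))
    if (any(sg < sd_floor))
      stop("EM degeneracy: component SD collapsed below the floor (",
           sd_floor, "); raise `sd_floor` or inspect the data",
           call. = FALSE)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  w <- w[ord]; mu <- mu[ord]; sg <- sg[ord]
  thr <- mixture_threshold(w, mu, sg)
  structure(list(weights = w, means = mu, sds = sg, threshold = thr,
                 loglik = ll_trace, iterations = length(ll_trace)),
            class = "mixture_fit")
}

## Root of w1 N(x|m1,s1) = w2 N(x|m2,s2) lying strictly between the means.
mixture_threshold <- function(w, mu, sg) {
  if (abs(mu[2L] - mu[1L]) < 1e-12)
    stop("threshold undefined: component means coincide", call. = FALSE)
  ## equate log weighted densities:
  ## a x^2 + b x + cc = 0 with coefficients below
  a <- 1 / (2 * sg[1L]^2) - 1 / (2 * sg[2L]^2)
  if (abs(a) < 1e-14) {
    ## equal variances: the equation is linear
    b1 <- (mu[2L] - mu[1L]) / sg[1L]^2
    c1 <- (mu[1L]^2 - mu[2L]^2) / (2 * sg[1L]^2) + log(w[2L] / w[1L])
    root <- -c1 / b1
    if (root <= mu[1L] || root >= mu[2L])
      stop("no density intersection between the means", call. = FALSE)
    return(root)
  }
  b <- -mu[1L] / sg[1L]^2 + mu[2L] / sg[2L]^2
  cc <- mu[1L]^2 / (2 * sg[1L]^2) - mu[2L]^2 / (2 * sg[2L]^2) -
    log(w[1L] * sg[2L] / (w[2L] * sg[1L]))
  disc <- b^2 - 4 * a * cc
  if (disc < 0)
    stop("no density intersection between the means", call. = FALSE)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu[1L] & roots < mu[2L]]
  if (length(inside) == 0L)
    stop("no density intersection between the means", call. = FALSE)
  inside[1L]
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit> components N(%.4g, %.3g) w=%.3f | ",
                     "N(%.4g, %.3g) w=%.3f\n"),
              x$means[1L], x$sds[1L], x$weights[1L],
              x$means[2L], x$sds[2L], x$weights[2L]))
  cat(sprintf("  threshold %.4g after %d EM iterations (loglik %.4g)\n",
              x$threshold, x$iterations, x$loglik[length(x$loglik)]))
  invisible(x)
}

#' Fraction of cells above a gating threshold
#'
#' The positivity fraction is the proportion of per-cell statistics
#' strictly above the threshold; its complement is the low-expresser
#' fraction.
#'
#' @param stats numeric vector of per-cell statistics (nonempty).
#' @param threshold gating threshold (e.g. `fit$threshold` from
#'   [fit_two_gaussians()]).
#' @return fraction in \[0, 1\].
#' @export
positivity_fraction <- function(stats, threshold) {
  if (length(stats) == 0L) stop("empty statistics vector", call. = FALSE)
  mean(stats > threshold)
}
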