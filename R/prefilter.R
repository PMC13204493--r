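#' Prefilter configuration
#'
#' Parameters of the five-stage candidate prefilter. Defaults target
#' lymphocyte-scale cells (7--15 um diameter, i.e. 21--46 px radius) at the
#' instrument's 0.1625 um/px sample-plane scale. The texture (local SD)
#' response of a ring-contrast cell is an elevated region with a quieter
#' core whose inner transition sits at a similar radius across the cell
#' size range; the default annulus template (outer radius 20 px, inner
#' 0.4 of that) targets that transition, which keeps the correlation peak
#' centered for both small and large cells. Peak spacing defaults to
#' 31 px, about the median cell radius, so one cell yields one peak. All
#' stages are deterministic.
#'
#' @param std_window_px odd window side of the local standard-deviation
#'   filter (px). Chosen near the ring-contrast rim width so the filter
#'   rectifies contrast polarity without smearing neighboring cells.
#' @param template_radius_px outer radius of the match template (px).
#' @param template_kind `"annulus"` (default; matches the ring-shaped
#'   texture response of defocused cells) or `"disc"`.
#' @param annulus_inner_frac inner radius of the annulus template as a
#'   fraction of `template_radius_px`.
#' @param threshold match-filter responses below `max(0, threshold)` are
#'   zeroed (negative-value thresholding).
#' @param min_peak_distance_px minimum Euclidean separation between
#'   accepted local maxima (px).
#' @param segment_radius_px maximum radial extent of a segmented candidate
#'   (px).
#' @param n_rays number of equally spaced rays cast during radial
#'   segmentation.
#' @param boundary_frac the per-ray boundary is the first radius where the
#'   absolute deviation from local background falls below this fraction of
#'   the center deviation.
#' @param min_center_snr a peak is segmented only if its center deviation
#'   (mean of the 3 x 3 patch) exceeds this multiple of the standard error
#'   implied by the local background spread; suppresses contrast-free
#'   noise peaks.
#' @param min_area_px,max_area_px accepted mask area bounds (px^2).
#' @return list of class `prefilter_config`.
#' @export
prefilter_config <- function(std_window_px = 7L,
                             template_radius_px = 20L,
                             template_kind = c("annulus", "disc"),
                             annulus_inner_frac = 0.4,
                             threshold = 0,
                             min_peak_distance_px = 31L,
                             segment_radius_px = 45L,
                             n_rays = 32L,
                             boundary_frac = 0.2,
                             min_center_snr = 5,
                             min_area_px = 150,
                             max_area_px = 6000) {
  template_kind <- match.arg(template_kind)
  std_window_px <- as.integer(std_window_px)
  if (std_window_px %% 2L == 0L || std_window_px < 3L)
    stop("`std_window_px` must be odd and >= 3", call. = FALSE)
  if (template_radius_px < 1) stop("`template_radius_px` must be >= 1",
                                   call. = FALSE)
  if (min_peak_distance_px < 1) stop("`min_peak_distance_px` must be >= 1",
                                     call. = FALSE)
  if (!(min_area_px > 0 && min_area_px < max_area_px))
    stop("need 0 < min_area_px < max_area_px", call. = FALSE)
  structure(list(std_window_px = std_window_px,
                 template_radius_px = template_radius_px,
                 template_kind = template_kind,
                 annulus_inner_frac = annulus_inner_frac,
                 threshold = threshold,
                 min_peak_distance_px = min_peak_distance_px,
                 segment_radius_px = segment_radius_px,
                 n_rays = as.integer(n_rays),
                 boundary_frac = boundary_frac,
                 min_center_snr = min_center_snr,
                 min_area_px = min_area_px,
                 max_area_px = max_area_px),
            class = "prefilter_config")
}

## ---- internal numerics ----------------------------------------------------

## Mirror (symmetric, edge included) padding: for n columns padded by p,
## column order is p..1, 1..n, n..n-p+1. Requires p <= n.
reflect_pad <- function(m, p1, p2 = p1) {
  n1 <- nrow(m); n2 <- ncol(m)
  if (p1 > n1 || p2 > n2)
    stop("padding exceeds image size", call. = FALSE)
  ri <- c(if (p1 > 0L) p1:1L, 1L:n1, if (p1 > 0L) n1:(n1 - p1 + 1L))
  ci <- c(if (p2 > 0L) p2:1L, 1L:n2, if (p2 > 0L) n2:(n2 - p2 + 1L))
  m[ri, ci, drop = FALSE]
}

## Sliding sums of length-w windows along each column.
row_box <- function(m, w) {
  cs <- apply(m, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = nrow(m))
  cs <- rbind(0, cs)
  cs[(w + 1L):nrow(cs), , drop = FALSE] - cs[1L:(nrow(cs) - w), , drop = FALSE]
}

box_sum <- function(m, w) t(row_box(t(row_box(m, w)), w))

## Circular cross-correlation out[i,j] = sum_uv x[i+u, j+v] k[u,v] with the
## kernel centered at offset (0, 0), via FFT.
circ_correlate <- function(xp, k) {
  n1 <- nrow(xp); n2 <- ncol(xp)
  h1 <- (nrow(k) - 1L) %/% 2L; h2 <- (ncol(k) - 1L) %/% 2L
  kp <- matrix(0, n1, n2)
  ri <- ((seq_len(nrow(k)) - 1L - h1) %% n1) + 1L
  ci <- ((seq_len(ncol(k)) - 1L - h2) %% n2) + 1L
  kp[ri, ci] <- k
  Re(stats::fft(stats::fft(xp) * Conj(stats::fft(kp)), inverse = TRUE)) /
    (n1 * n2)
}

## Same-size cross-correlation with mirror-padded borders.
correlate2 <- function(x, k) {
  h1 <- (nrow(k) - 1L) %/% 2L; h2 <- (ncol(k) - 1L) %/% 2L
  xp <- reflect_pad(x, h1, h2)
  out <- circ_correlate(xp, k)
  out[(h1 + 1L):(h1 + nrow(x)), (h2 + 1L):(h2 + ncol(x)), drop = FALSE]
}

## Rotationally symmetric match template and its support mask. Both kinds
## must be non-constant over the support (zero-mean correlation is
## undefined for a flat template): "disc" is a uniform inner disc (0.7 r)
## inside a background ring out to r; "annulus" is a uniform ring from
## inner_frac * r to r with a hollow core.
make_template <- function(radius, kind = "annulus", inner_frac = 0.6) {
  r <- seq(-radius, radius)
  rho <- sqrt(outer(r^2, r^2, `+`))
  support <- rho <= radius + 1e-9
  vals <- matrix(0, length(r), length(r))
  if (kind == "disc") {
    vals[support & rho <= 0.7 * radius] <- 1
  } else {
    vals[support & rho > inner_frac * radius] <- 1
  }
  list(values = vals, support = support)
}

## ---- the five stages ------------------------------------------------------

#' Stage 1: local standard-deviation filter
#'
#' Assigns each pixel the population standard deviation of the
#' `window_px` x `window_px` window centered on it (mirror padding at the
#' borders). Rectifies contrast polarity: both bright-center and
#' dark-center cells map to positive texture responses.
#'
#' @param image a [carfind_image] or numeric matrix.
#' @param window_px odd window side, at most `min(dim(image))`.
#' @return numeric matrix of the same shape.
#' @export
local_std_filter <- function(image, window_px) {
  x <- as_pixels(image)
  window_px <- as.integer(window_px)
  if (window_px %% 2L == 0L)
    stop("`window_px` must be odd", call. = FALSE)
  if (window_px > min(dim(x)))
    stop("`window_px` exceeds the smallest image dimension", call. = FALSE)
  h <- (window_px - 1L) %/% 2L
  xp <- reflect_pad(x, h, h)
  n <- as.numeric(window_px)^2
  m1 <- box_sum(xp, window_px) / n
  m2 <- box_sum(xp * xp, window_px) / n
  v <- m2 - m1 * m1
  v[v < 0] <- 0
  sqrt(v)
}

#' Stage 2: modified match filter
#'
#' Zero-mean normalized cross-correlation of the stage-1 texture response
#' with a rotationally symmetric template (disc or annulus). Template and
#' each local window are mean-subtracted over the template support, so flat
#' background scores 0 and the output lies in \[-1, 1\]. Borders use mirror
#' padding; windows with vanishing variance score 0.
#'
#' @param response numeric matrix (normally the [local_std_filter()] output).
#' @param config a [prefilter_config].
#' @return correlation matrix of the same shape, values in \[-1, 1\].
#' @export
match_filter <- function(response, config = prefilter_config()) {
  x <- as_pixels(response)
  r <- config$template_radius_px
  if (2L * r + 1L > min(dim(x)))
    stop("template larger than image", call. = FALSE)
  tpl <- make_template(r, config$template_kind, config$annulus_inner_frac)
  s <- tpl$support * 1.0
  n <- sum(s)
  t0 <- (tpl$values - sum(tpl$values[tpl$support]) / n) * s
  tnorm <- sqrt(sum(t0^2))
  num <- correlate2(x, t0)
  sx <- correlate2(x, s)
  sxx <- correlate2(x * x, s)
  varw <- sxx - sx * sx / n
  varw[varw < 0] <- 0
  den <- sqrt(varw) * tnorm
  out <- matrix(0, nrow(x), ncol(x))
  ## relative floor: FFT roundoff in sxx - sx^2/n scales with the window
  ## energy, so flat windows must be excluded on a relative scale
  ok <- varw > 1e-10 * (sxx + 1)
  out[ok] <- num[ok] / den[ok]
  pmin(pmax(out, -1), 1)
}

#' Stage 3: negative-value thresholding
#'
#' Replaces every value below `max(0, threshold)` by 0; values at or above
#' the cut are kept unchanged.
#'
#' @param correlation numeric matrix.
#' @param threshold scalar cut; negative values are always removed.
#' @return thresholded matrix.
#' @export
negative_threshold <- function(correlation, threshold = 0) {
  x <- as_pixels(correlation)
  cut <- max(0, threshold)
  x[x < cut] <- 0
  x
}

#' Stage 4: local-maxima identification
#'
#' Returns strictly positive pixels that are maximal within their
#' `(2 * min_distance + 1)` square neighborhood, greedily suppressed so no
#' two accepted peaks lie closer than `min_distance_px` (Euclidean).
#' Output is sorted by descending score, ties broken by (row, col).
#'
#' @param thresholded numeric matrix (stage-3 output).
#' @param min_distance_px minimum separation, >= 1.
#' @return data frame with columns `row`, `col`, `score`.
#' @export
find_local_maxima <- function(thresholded, min_distance_px) {
  x <- as_pixels(thresholded)
  d <- as.integer(min_distance_px)
  if (d < 1L) stop("`min_distance_px` must be >= 1", call. = FALSE)
  mx <- max_filter(x, d)
  idx <- which(x > 0 & x >= mx, arr.ind = TRUE)
  empty <- data.frame(row = integer(), col = integer(), score = numeric())
  if (nrow(idx) == 0L) return(empty)
  sc <- x[idx]
  ord <- order(-sc, idx[, 1L], idx[, 2L])
  rs <- idx[ord, 1L]; cs <- idx[ord, 2L]; sc <- sc[ord]
  accr <- numeric(0); accc <- numeric(0); accs <- numeric(0)
  d2 <- as.numeric(d)^2
  for (i in seq_along(sc)) {
    if (length(accr) == 0L ||
        all((accr - rs[i])^2 + (accc - cs[i])^2 >= d2)) {
      accr <- c(accr, rs[i]); accc <- c(accc, cs[i]); accs <- c(accs, sc[i])
    }
  }
  data.frame(row = as.integer(accr), col = as.integer(accc), score = accs)
}

## Square-window dilation (max filter) with half-width d; borders see -Inf.
max_filter <- function(x, d) {
  out <- x
  n1 <- nrow(x); n2 <- ncol(x)
  shift <- function(m, dr, dc) {
    res <- matrix(-Inf, n1, n2)
    rsrc <- max(1L, 1L - dr):min(n1, n1 - dr)
    csrc <- max(1L, 1L - dc):min(n2, n2 - dc)
    res[rsrc, csrc] <- m[rsrc + dr, csrc + dc]
    res
  }
  for (k in seq_len(d)) out <- pmax(out, shift(x, -k, 0L), shift(x, k, 0L))
  rowmax <- out
  for (k in seq_len(d)) out <- pmax(out, shift(rowmax, 0L, -k),
                                    shift(rowmax, 0L, k))
  out
}

#' Stage 5: radial segmentation
#'
#' For each peak, casts `n_rays` equally spaced rays outward over the
#' original brightfield tile. The local background is the median intensity
#' in a thin ring at `segment_radius_px`; on each ray the boundary is the
#' first radius where the absolute deviation from that background falls
#' below `boundary_frac` of its value at the peak. The mask is the
#' star-shaped region enclosed by the per-ray boundaries (linear angular
#' interpolation). Candidates whose mask area falls outside
#' `[min_area_px, max_area_px]` are discarded; overlapping masks are never
#' merged -- each peak yields its own candidate.
#'
#' @param image original brightfield tile ([carfind_image] or matrix).
#' @param peaks data frame with columns `row`, `col`, `score`
#'   (from [find_local_maxima()]).
#' @param config a [prefilter_config].
#' @return list of candidates; each is a list with `center` (row, col),
#'   `radius_px` (equivalent radius), `area_px`, `crop` (square sub-image,
#'   mask bounding box padded by 2 px), `mask` (logical, crop-aligned),
#'   `bbox` (top-left row/col of the crop in the tile, 1-based),
#'   `peak_score`, `label`, `features`.
#' @export
radial_segment <- function(image, peaks, config = prefilter_config()) {
  x <- as_pixels(image)
  n1 <- nrow(x); n2 <- ncol(x)
  if (nrow(peaks) > 0 &&
      (any(peaks$row < 1 | peaks$row > n1 | peaks$col < 1 | peaks$col > n2)))
    stop("peak outside image", call. = FALSE)
  R <- config$segment_radius_px
  N <- config$n_rays
  frac <- config$boundary_frac
  theta <- 2 * pi * (seq_len(N) - 1L) / N
  rho_samples <- seq(1, R, by = 0.5)
  out <- vector("list", nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    r0 <- peaks$row[p]; c0 <- peaks$col[p]
    rr <- max(1L, r0 - R):min(n1, r0 + R)
    cc <- max(1L, c0 - R):min(n2, c0 + R)
    patch <- x[rr, cc, drop = FALSE]
    dr <- outer(rr - r0, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - c0)
    rho <- sqrt(dr^2 + dc^2)
    ring <- rho >= 0.85 * R & rho <= R
    ring_px <- if (any(ring)) patch[ring] else patch
    bg <- stats::median(ring_px)
    sigma_bg <- stats::mad(ring_px)
    ## center deviation from a 3 x 3 mean: robust to single-pixel noise
    cr3 <- max(1L, r0 - 1L):min(n1, r0 + 1L)
    cc3 <- max(1L, c0 - 1L):min(n2, c0 + 1L)
    npatch <- length(cr3) * length(cc3)
    dev_center <- mean(x[cr3, cc3]) - bg
    if (abs(dev_center) < 1e-9 ||
        abs(dev_center) < config$min_center_snr * sigma_bg / sqrt(npatch))
      next
    cutoff <- frac * abs(dev_center)
    bound <- numeric(N)
    for (j in seq_len(N)) {
      pr <- pmin(pmax(round(r0 + rho_samples * sin(theta[j])), 1L), n1)
      pc <- pmin(pmax(round(c0 + rho_samples * cos(theta[j])), 1L), n2)
      dev <- abs(x[cbind(pr, pc)] - bg)
      hit <- which(dev < cutoff)
      bound[j] <- if (length(hit)) rho_samples[hit[1L]] else R
    }
    ## star-shaped fill: pixel is inside if its radius is below the
    ## angularly interpolated boundary at its direction
    phi <- atan2(dr, dc) %% (2 * pi)
    j0 <- floor(phi / (2 * pi / N))
    frac_ang <- phi / (2 * pi / N) - j0
    b0 <- bound[(j0 %% N) + 1L]
    b1 <- bound[((j0 + 1L) %% N) + 1L]
    blim <- b0 * (1 - frac_ang) + b1 * frac_ang
    mask <- rho <= blim
    area <- sum(mask)
    if (area < config$min_area_px || area > config$max_area_px) next
    mr <- range(which(rowSums(mask) > 0))
    mc <- range(which(colSums(mask) > 0))
    gr <- c(rr[mr[1L]], rr[mr[2L]]); gc <- c(cc[mc[1L]], cc[mc[2L]])
    gr <- c(max(1L, gr[1L] - 2L), min(n1, gr[2L] + 2L))
    gc <- c(max(1L, gc[1L] - 2L), min(n2, gc[2L] + 2L))
    crop <- x[gr[1L]:gr[2L], gc[1L]:gc[2L], drop = FALSE]
    mfull <- matrix(FALSE, n1, n2)
    mfull[rr, cc] <- mask
    mcrop <- mfull[gr[1L]:gr[2L], gc[1L]:gc[2L], drop = FALSE]
    ## report the mask centroid: the match-filter peak can sit anywhere on
    ## a broad correlation plateau, the centroid recenters on the object
    midx <- which(mask, arr.ind = TRUE)
    ctr <- c(row = mean(rr[midx[, 1L]]), col = mean(cc[midx[, 2L]]))
    out[[p]] <- list(center = ctr,
                     radius_px = sqrt(area / pi),
                     area_px = area,
                     crop = crop, mask = mcrop,
                     bbox = c(row = gr[1L], col = gc[1L]),
                     peak_score = peaks$score[p],
                     label = NULL, features = NULL)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Detect candidate objects in a brightfield tile
#'
#' Exact composition of the five prefilter stages:
#' [local_std_filter()] -> [match_filter()] -> [negative_threshold()] ->
#' [find_local_maxima()] -> [radial_segment()]. Deterministic for fixed
#' input and configuration. Each surviving candidate also receives its
#' feature vector (see [extract_features()]), computed from the raw crop
#' and the stage-1 texture response.
#'
#' @param image a [carfind_image] or numeric matrix.
#' @param config a [prefilter_config].
#' @param keep_stages if `TRUE`, attach the intermediate grids as the
#'   `"stages"` attribute (named list `std`, `correlation`, `thresholded`,
#'   `peaks`) for inspection or export via [write_response()].
#' @return list of candidates (see [radial_segment()]), each with
#'   `features` filled.
#' @export
detect_candidates <- function(image, config = prefilter_config(),
                              keep_stages = FALSE) {
  x <- as_pixels(image)
  std <- local_std_filter(x, config$std_window_px)
  corr <- match_filter(std, config)
  thr <- negative_threshold(corr, config$threshold)
  peaks <- find_local_maxima(thr, config$min_peak_distance_px)
  cands <- radial_segment(x, peaks, config)
  cands <- lapply(cands, function(cd) {
    cd$features <- extract_features(cd, std)
    cd
  })
  if (keep_stages)
    attr(cands, "stages") <- list(std = std, correlation = corr,
                                  thresholded = thr, peaks = peaks)
  cands
}
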