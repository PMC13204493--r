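#' Synthetic scene configuration
#'
#' Parameters of the ground-truthed brightfield tile generator. Defaults
#' emulate the acquisition geometry (6.5 um camera pixel, 40x objective,
#' hence 0.1625 um/px) on a 512 x 512 test tile, with lymphocyte-scale
#' ring-contrast cells (7--15 um), small low-contrast platelets (2--4 um),
#' residual biconcave-profile RBCs (6--8 um) and irregular debris blobs.
#' Object counts per tile are Poisson with the configured densities.
#'
#' @param geometry an [imaging_geometry()]; its `view_px` sets the tile
#'   size and its `sample_pixel_um` the physical scale.
#' @param background_level mean background intensity (16-bit counts).
#' @param read_noise_sd additive Gaussian read noise SD (counts).
#' @param densities named vector of expected objects per tile for each of
#'   [object_classes()].
#' @param cell_diameter_um_range,platelet_diameter_um_range,
#'   rbc_diameter_um_range,other_diameter_um_range sampled physical
#'   diameter ranges (um).
#' @param cell_contrast peak ring amplitude relative to the background
#'   level; the tile signal-to-noise ratio is
#'   `cell_contrast * background_level / read_noise_sd` (8 at defaults).
#' @param contrast_polarity `"bright_center"` (default) or `"dark_center"`;
#'   brightfield contrast flips with defocus direction.
#' @param crowding minimum center-to-center spacing in px (0 allows
#'   touching objects).
#' @param seed RNG seed.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(geometry = imaging_geometry(view_px = c(512L, 512L)),
                         background_level = 10000,
                         read_noise_sd = 100,
                         densities = c(CART = 10, PLATELET = 15, RBC = 5,
                                       OTHER = 5),
                         cell_diameter_um_range = c(7, 15),
                         platelet_diameter_um_range = c(2, 4),
                         rbc_diameter_um_range = c(6, 8),
                         other_diameter_um_range = c(4, 12),
                         cell_contrast = 0.08,
                         contrast_polarity = c("bright_center",
                                               "dark_center"),
                         crowding = 40,
                         seed = 20240101L) {
  contrast_polarity <- match.arg(contrast_polarity)
  dens <- stats::setNames(rep(0, length(object_classes())),
                          object_classes())
  dens[names(densities)] <- densities
  if (any(dens < 0)) stop("densities must be >= 0", call. = FALSE)
  rng_ok <- function(r) length(r) == 2L && all(r > 0) && r[1L] <= r[2L]
  stopifnot(rng_ok(cell_diameter_um_range),
            rng_ok(platelet_diameter_um_range),
            rng_ok(rbc_diameter_um_range),
            rng_ok(other_diameter_um_range))
  if (background_level * (1 + 2 * cell_contrast) > 65535)
    stop("background + contrast amplitude exceeds the 16-bit range",
         call. = FALSE)
  structure(list(geometry = geometry,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 densities = dens,
                 cell_diameter_um_range = cell_diameter_um_range,
                 platelet_diameter_um_range = platelet_diameter_um_range,
                 rbc_diameter_um_range = rbc_diameter_um_range,
                 other_diameter_um_range = other_diameter_um_range,
                 cell_contrast = cell_contrast,
                 contrast_polarity = contrast_polarity,
                 crowding = crowding,
                 seed = as.integer(seed)),
            class = "scene_config")
}

diameter_range_of <- function(config, class) {
  switch(class,
         CART = config$cell_diameter_um_range,
         PLATELET = config$platelet_diameter_um_range,
         RBC = config$rbc_diameter_um_range,
         OTHER = config$other_diameter_um_range)
}

## Radial intensity profiles, per class, as deviation from background.
## rho_hat = radius / object radius; A = cell_contrast * background.
profile_of <- function(class, rho_hat, A, pars = NULL) {
  switch(class,
         CART = A * exp(-(rho_hat / 0.45)^4) -
           0.8 * A * exp(-((rho_hat - 0.85) / 0.15)^2),
         PLATELET = 0.35 * A * exp(-(rho_hat / 0.5)^2),
         RBC = -0.25 * A * exp(-(rho_hat / 0.5)^4) -
           0.7 * A * exp(-((rho_hat - 0.8) / 0.15)^2),
         stop("no radial profile for class ", class))
}

## Place n centers with minimum spacing inside [margin, dim - margin].
## Greedy rejection sampling with whole-placement restarts; errors only
## when the requested density is genuinely incompatible with the spacing.
place_centers <- function(n, dims, margins, spacing, max_tries = 500L,
                          max_restarts = 25L) {
  for (attempt in seq_len(max_restarts)) {
    rows <- numeric(0); cols <- numeric(0)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        r <- stats::runif(1, margins[i], dims[1L] - margins[i])
        c <- stats::runif(1, margins[i], dims[2L] - margins[i])
        if (length(rows) == 0L ||
            all((rows - r)^2 + (cols - c)^2 >= spacing^2)) {
          rows <- c(rows, r); cols <- c(cols, c)
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(cbind(row = rows, col = cols))
  }
  ## rejection sampling saturates well below the packing limit; fall back
  ## to a jittered grid whose pitch guarantees the spacing constraint
  mg <- max(margins)
  if (spacing > 0) {
    pitch <- spacing * 1.15
    jit <- 0.07 * spacing
    gr <- seq(mg, dims[1L] - mg, by = pitch)
    gc <- seq(mg, dims[2L] - mg, by = pitch)
    sites <- expand.grid(row = gr, col = gc)
    if (n <= nrow(sites)) {
      pick <- sites[sample.int(nrow(sites), n), ]
      return(cbind(row = pick$row + stats::runif(n, -jit, jit),
                   col = pick$col + stats::runif(n, -jit, jit)))
    }
  }
  stop("placement failure: requested density incompatible with the ",
       "crowding constraint", call. = FALSE)
}

## Add one object's profile to the tile (in place semantics via return).
render_object <- function(tile, class, center, radius_px, A, polarity) {
  n1 <- nrow(tile); n2 <- ncol(tile)
  ext <- ceiling(1.4 * radius_px)
  rr <- max(1L, floor(center[1L] - ext)):min(n1, ceiling(center[1L] + ext))
  cc <- max(1L, floor(center[2L] - ext)):min(n2, ceiling(center[2L] + ext))
  rho <- sqrt(outer((rr - center[1L])^2, (cc - center[2L])^2, `+`)) /
    radius_px
  if (class == "OTHER") {
    ## irregular debris: 2-4 off-center blobs, mixed polarity, one anchored
    ## near the center so the object is seeded where the truth says
    nb <- sample(2:4, 1L)
    dev <- matrix(0, length(rr), length(cc))
    for (b in seq_len(nb)) {
      off_r <- if (b == 1L) 0.25 else 0.8
      ang <- stats::runif(1, 0, 2 * pi)
      orad <- stats::runif(1, 0, off_r)
      br <- center[1L] + orad * radius_px * sin(ang)
      bc <- center[2L] + orad * radius_px * cos(ang)
      amp <- stats::runif(1, 0.4, 0.9) * A * sample(c(-1, 1), 1L)
      if (b == 1L) amp <- abs(amp)
      sig <- stats::runif(1, 0.3, 0.6) * radius_px
      d2 <- outer((rr - br)^2, (cc - bc)^2, `+`)
      dev <- dev + amp * exp(-d2 / (2 * sig^2))
    }
  } else {
    dev <- profile_of(class, rho, A)
    dev[rho > 1.3] <- 0
  }
  if (polarity == "dark_center") dev <- -dev
  tile[rr, cc] <- tile[rr, cc] + dev
  tile
}

#' Render a synthetic brightfield tile with ground truth
#'
#' Draws Poisson object counts at the configured densities, places objects
#' with the crowding constraint, renders the per-class radial profiles,
#' adds Gaussian read noise, and clamps to the 16-bit range. Deterministic
#' for a fixed seed.
#'
#' @param config a [scene_config].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with `image` (a [carfind_image]) and `truth` (data frame
#'   with columns `class`, `row`, `col`, `radius_px`, `contrast`).
#' @export
render_tile <- function(config = scene_config(), seed = config$seed) {
  set.seed(seed)
  dims <- config$geometry$view_px
  px_um <- config$geometry$sample_pixel_um
  A <- config$cell_contrast * config$background_level
  counts <- vapply(object_classes(),
                   function(cl) stats::rpois(1L, config$densities[[cl]]),
                   0L)
  classes <- rep(object_classes(), counts)
  n <- length(classes)
  truth <- data.frame(class = character(0), row = numeric(0),
                      col = numeric(0), radius_px = numeric(0),
                      contrast = numeric(0))
  tile <- matrix(config$background_level, dims[1L], dims[2L])
  if (n > 0L) {
    classes <- sample(classes)  # interleave placement order
    radii <- vapply(classes, function(cl) {
      dr <- diameter_range_of(config, cl)
      stats::runif(1, dr[1L], dr[2L]) / 2 / px_um
    }, 0)
    centers <- place_centers(n, dims, margins = radii + 3,
                             spacing = config$crowding)
    for (i in seq_len(n))
      tile <- render_object(tile, classes[i], centers[i, ], radii[i], A,
                            config$contrast_polarity)
    truth <- data.frame(class = classes,
                        row = centers[, "row"], col = centers[, "col"],
                        radius_px = radii,
                        contrast = A, stringsAsFactors = FALSE)
  }
  tile <- tile + stats::rnorm(length(tile), 0, config$read_noise_sd)
  tile <- round(pmin(pmax(tile, 0), 65535))
  list(image = carfind_image(tile, pixel_size_um = px_um,
                             name = sprintf("synthetic_seed%d", seed)),
       truth = truth)
}

#' Render the paired fluorescence tile
#'
#' CART-class objects are CAR-positive with probability
#' `positive_fraction`; positives receive 3--8 bright punctate dots
#' (clustered receptor signal) within 0.7 of their footprint radius, while
#' negatives and non-CART objects show only uniform dim autofluorescence.
#' Coordinates are shared with the brightfield tile.
#'
#' @param truth truth data frame from [render_tile()].
#' @param dims tile size (rows, cols).
#' @param positive_fraction probability that a CART object is positive.
#' @param dot_model list: `n_range` (dot count range), `amplitude`,
#'   `sigma_px` (dot Gaussian width), `dim_level` (autofluorescence
#'   amplitude).
#' @param background_level,read_noise_sd background and noise (counts).
#' @param seed RNG seed.
#' @return list with `image` (a [carfind_image]) and `positive` (logical
#'   per truth row; `FALSE` for non-CART objects).
#' @export
render_fluor <- function(truth, dims = c(512L, 512L),
                         positive_fraction = 0.88,
                         dot_model = list(n_range = c(3L, 8L),
                                          amplitude = 3000,
                                          sigma_px = 2.5,
                                          dim_level = 150),
                         background_level = 500, read_noise_sd = 30,
                         seed = 20240101L) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1)
  set.seed(seed)
  tile <- matrix(background_level, dims[1L], dims[2L])
  positive <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    r0 <- truth$row[i]; c0 <- truth$col[i]; rad <- truth$radius_px[i]
    ext <- ceiling(rad)
    rr <- max(1L, floor(r0 - ext)):min(dims[1L], ceiling(r0 + ext))
    cc <- max(1L, floor(c0 - ext)):min(dims[2L], ceiling(c0 + ext))
    rho <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    ## dim autofluorescence disc for every object
    tile[rr, cc] <- tile[rr, cc] + dot_model$dim_level * (rho <= rad)
    if (truth$class[i] == "CART" &&
        stats::runif(1) < positive_fraction) {
      positive[i] <- TRUE
      nd <- sample(dot_model$n_range[1L]:dot_model$n_range[2L], 1L)
      for (d in seq_len(nd)) {
        ang <- stats::runif(1, 0, 2 * pi)
        drad <- stats::runif(1, 0, 0.7 * rad)
        dr <- r0 + drad * sin(ang); dc <- c0 + drad * cos(ang)
        d2 <- outer((rr - dr)^2, (cc - dc)^2, `+`)
        tile[rr, cc] <- tile[rr, cc] +
          dot_model$amplitude * exp(-d2 / (2 * dot_model$sigma_px^2))
      }
    }
  }
  tile <- tile + stats::rnorm(length(tile), 0, read_noise_sd)
  tile <- round(pmin(pmax(tile, 0), 65535))
  list(image = carfind_image(tile, name = sprintf("fluor_seed%d", seed)),
       positive = positive)
}

#' Build a labeled synthetic object library
#'
#' Renders `n_per_class` single-object scenes for each of the four
#' categories, segments each object at its known center (relaxed area
#' bounds, mirroring interactive labeling of real crops), extracts
#' features, and partitions the crops into disjoint train/test sets.
#'
#' @param n_per_class crops per category (default 150).
#' @param split (train, test) counts summing to `n_per_class`
#'   (default 100/50).
#' @param config a [scene_config]; its contrast/noise set the library's
#'   operating point.
#' @param prefilter a [prefilter_config] supplying segmentation and match
#'   template parameters.
#' @param seed RNG seed.
#' @return list with `train` and `test`, each a list of `features`
#'   (matrix), `labels` (character), `ids` (globally unique integers);
#'   plus `n_per_class` and `split`.
#' @export
make_object_library <- function(n_per_class = 150L, split = c(100L, 50L),
                                config = scene_config(),
                                prefilter = prefilter_config(),
                                seed = 20240101L) {
  if (sum(split) != n_per_class)
    stop("`split` must sum to `n_per_class`", call. = FALSE)
  set.seed(seed)
  px_um <- config$geometry$sample_pixel_um
  A <- config$cell_contrast * config$background_level
  seg_cfg <- prefilter
  seg_cfg$min_area_px <- 5
  seg_cfg$max_area_px <- Inf
  L <- 2L * as.integer(seg_cfg$segment_radius_px) + 102L  # single-object tile
  feats <- list(); labels <- character(0)
  for (cl in object_classes()) {
    for (k in seq_len(n_per_class)) {
      dr <- diameter_range_of(config, cl)
      rad <- stats::runif(1, dr[1L], dr[2L]) / 2 / px_um
      center <- round(L / 2 + stats::runif(2, -8, 8))
      tile <- matrix(config$background_level, L, L)
      tile <- render_object(tile, cl, center, rad, A,
                            config$contrast_polarity)
      tile <- tile + stats::rnorm(length(tile), 0, config$read_noise_sd)
      tile <- round(pmin(pmax(tile, 0), 65535))
      std <- local_std_filter(tile, seg_cfg$std_window_px)
      score <- zncc_at(std, center, seg_cfg)
      cands <- radial_segment(tile,
                              data.frame(row = center[1L],
                                         col = center[2L],
                                         score = score),
                              seg_cfg)
      cand <- if (length(cands)) cands[[1L]] else
        disc_candidate(tile, center, max(3, 0.5 * rad), score)
      feats[[length(feats) + 1L]] <- extract_features(cand, std)
      labels <- c(labels, cl)
    }
  }
  fm <- do.call(rbind, feats)
  ids <- seq_len(nrow(fm))
  tr_idx <- unlist(lapply(seq_along(object_classes()) - 1L, function(g)
    g * n_per_class + seq_len(split[1L])))
  te_idx <- setdiff(ids, tr_idx)
  list(train = list(features = fm[tr_idx, , drop = FALSE],
                    labels = labels[tr_idx], ids = ids[tr_idx]),
       test = list(features = fm[te_idx, , drop = FALSE],
                   labels = labels[te_idx], ids = ids[te_idx]),
       n_per_class = n_per_class, split = split)
}

## ZNCC of the match template against a single window (no FFT).
zncc_at <- function(response, center, config) {
  tpl <- make_template(config$template_radius_px, config$template_kind,
                       config$annulus_inner_frac)
  r <- config$template_radius_px
  n1 <- nrow(response); n2 <- ncol(response)
  rr <- (center[1L] - r):(center[1L] + r)
  cc <- (center[2L] - r):(center[2L] + r)
  if (rr[1L] < 1L || cc[1L] < 1L || rr[length(rr)] > n1 ||
      cc[length(cc)] > n2) return(0)
  w <- response[rr, cc][tpl$support]
  tv <- tpl$values[tpl$support]
  t0 <- tv - mean(tv)
  vw <- sum((w - mean(w))^2)
  if (vw < 1e-12) return(0)
  val <- sum(w * t0) / (sqrt(vw) * sqrt(sum(t0^2)))
  min(max(val, -1), 1)
}

## Fallback labeling mask: a disc at the known center (used when radial
## segmentation collapses on very low-contrast objects).
disc_candidate <- function(tile, center, radius, score) {
  n1 <- nrow(tile); n2 <- ncol(tile)
  ext <- ceiling(radius) + 2L
  rr <- max(1L, center[1L] - ext):min(n1, center[1L] + ext)
  cc <- max(1L, center[2L] - ext):min(n2, center[2L] + ext)
  rho <- sqrt(outer((rr - center[1L])^2, (cc - center[2L])^2, `+`))
  mask <- rho <= radius
  list(center = c(row = center[1L], col = center[2L]),
       radius_px = sqrt(sum(mask) / pi), area_px = sum(mask),
       crop = tile[rr, cc, drop = FALSE], mask = mask,
       bbox = c(row = rr[1L], col = cc[1L]),
       peak_score = score, label = NULL, features = NULL)
}

#' Calibration simulation configuration
#'
#' Count-table generator emulating the spiking experiments. The expected
#' captured count is `background_mean` plus a response term: with
#' `response = "linear"` (buffer preset) the term is
#' `capture_efficiency * effective_volume_ul * concentration^capture_exponent`;
#' with `response = "log"` (whole-blood preset) it is
#' `log_slope * ln(1 + concentration)`, a saturating capture response --
#' crowding and nonspecific competition on the sensor surface depress the
#' per-cell capture probability at high load, which is why whole-blood
#' curves are fitted logarithmically. Observed counts are
#' Poisson-distributed (optionally plus Gaussian spread). The buffer
#' preset has no background; the blood preset carries the high blank
#' background (> 100 counts) from nonspecifically captured leukocytes.
#'
#' @param concentrations spiked concentrations (cells/uL).
#' @param replicates replicates per concentration.
#' @param capture_efficiency fraction of cells in the effective volume that
#'   are captured and counted.
#' @param capture_exponent exponent of a sub-linear capture response
#'   (1 = proportional).
#' @param effective_volume_ul sample volume whose cells can be captured
#'   (the 7.1 uL channel volume).
#' @param response `"linear"` or `"log"` (see above).
#' @param log_slope slope of the saturating log response (counts per
#'   ln(cells/uL)).
#' @param background_mean,background_sd blank count model.
#' @param count_noise `"poisson"` or `"poisson+gaussian"`.
#' @param n_blanks non-spiked replicates.
#' @param preset `"buffer"` or `"blood"`; the blood preset switches to the
#'   log response and the high-background blank model.
#' @param seed RNG seed.
#' @return list of class `cal_sim_config`.
#' @export
cal_sim_config <- function(concentrations = c(1, 10, 100, 1000),
                           replicates = 3L,
                           capture_efficiency = 0.9,
                           capture_exponent = 1,
                           effective_volume_ul = 7.1,
                           response = c("linear", "log"),
                           log_slope = 65,
                           background_mean = 0,
                           background_sd = 0,
                           count_noise = c("poisson", "poisson+gaussian"),
                           n_blanks = 3L,
                           preset = c("buffer", "blood"),
                           seed = 20240101L) {
  preset <- match.arg(preset)
  count_noise <- match.arg(count_noise)
  response <- match.arg(response)
  if (preset == "blood") {
    response <- "log"
    background_mean <- 120
    background_sd <- 15
    count_noise <- "poisson+gaussian"
  }
  stopifnot(all(concentrations > 0), replicates >= 1L,
            capture_efficiency > 0, capture_efficiency <= 1,
            effective_volume_ul > 0)
  structure(list(concentrations = concentrations,
                 replicates = as.integer(replicates),
                 capture_efficiency = capture_efficiency,
                 capture_exponent = capture_exponent,
                 effective_volume_ul = effective_volume_ul,
                 response = response,
                 log_slope = log_slope,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 count_noise = count_noise,
                 n_blanks = as.integer(n_blanks),
                 preset = preset,
                 seed = as.integer(seed)),
            class = "cal_sim_config")
}

#' Simulate a calibration count table
#'
#' @param config a [cal_sim_config].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return data frame with columns `concentration` (0 for blanks),
#'   `replicate`, `true_count` (expected captured cells without
#'   background), `observed` (noisy count, floored at 0).
#' @export
simulate_calibration <- function(config = cal_sim_config(),
                                 seed = config$seed) {
  set.seed(seed)
  conc <- c(rep(config$concentrations, each = config$replicates),
            rep(0, config$n_blanks))
  repl <- c(rep(seq_len(config$replicates),
                times = length(config$concentrations)),
            seq_len(config$n_blanks))
  true_count <- ifelse(conc > 0,
                       if (config$response == "log")
                         config$log_slope * log(1 + conc)
                       else
                         config$capture_efficiency *
                           config$effective_volume_ul *
                           conc^config$capture_exponent,
                       0)
  expected <- true_count + config$background_mean
  observed <- stats::rpois(length(expected), expected)
  if (config$count_noise == "poisson+gaussian")
    observed <- observed + stats::rnorm(length(observed), 0,
                                        config$background_sd)
  observed <- pmax(0, round(observed))
  data.frame(concentration = conc, replicate = repl,
             true_count = true_count, observed = observed)
}
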