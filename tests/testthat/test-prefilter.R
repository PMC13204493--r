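test_that("local SD filter matches hand-computed and brute-force values", {
  # constant image has zero variance everywhere
  expect_true(all(local_std_filter(matrix(7, 9, 9), 3) == 0))

  # single bright pixel: center window is {9, 0 x 8}
  y <- matrix(0, 5, 5); y[3, 3] <- 9
  expect_equal(local_std_filter(y, 3)[3, 3], sqrt(mean((c(9, rep(0, 8)) - 1)^2)),
               tolerance = 1e-12)

  set.seed(10)
  for (rep in 1:8) {
    n <- sample(8:24, 1)
    w <- sample(c(3, 5, 7), 1)
    x <- matrix(runif(n * n), n, n)
    expect_lt(max(abs(local_std_filter(x, w) - oracle_local_std(x, w))), 1e-9)
  }
  expect_error(local_std_filter(matrix(0, 8, 8), 4), "odd")
  expect_error(local_std_filter(matrix(0, 4, 4), 5), "exceeds")
})

test_that("match filter equals the sliding-window normalized correlation oracle", {
  set.seed(11)
  for (kind in c("annulus", "disc")) {
    for (rep in 1:5) {
      x <- matrix(runif(32 * 32), 32, 32)
      r <- sample(3:5, 1)
      cfg <- prefilter_config(template_radius_px = r, template_kind = kind)
      expect_lt(max(abs(match_filter(x, cfg) -
                          oracle_zncc(x, r, kind, 0.4))), 1e-9)
    }
  }
})

test_that("match filter peaks at an embedded template copy and kills flat input", {
  cfg <- prefilter_config(template_radius_px = 4, template_kind = "annulus")
  tpl <- oracle_template(4, "annulus", 0.4)
  x <- matrix(0, 40, 40)
  x[12:20, 15:23] <- tpl$values
  corr <- match_filter(x, cfg)
  peak <- which(corr == max(corr), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(16L, 19L))

  expect_true(all(match_filter(matrix(5, 30, 30), cfg) == 0))
  expect_error(match_filter(matrix(0, 5, 5), prefilter_config(
    template_radius_px = 10)), "larger than image")
})

test_that("negative thresholding zeroes below the cut and keeps the rest", {
  expect_equal(negative_threshold(matrix(c(-1, 0, 0.5), 1)),
               matrix(c(0, 0, 0.5), 1))
  expect_true(all(negative_threshold(matrix(-runif(25), 5, 5)) == 0))
  expect_equal(negative_threshold(matrix(c(0.1, 0.4), 1), 0.3),
               matrix(c(0, 0.4), 1))
  # a negative cut still removes negatives
  expect_equal(negative_threshold(matrix(c(-0.2, 0.2), 1), -5),
               matrix(c(0, 0.2), 1))
})

test_that("local maxima match the greedy brute-force oracle", {
  expect_equal(nrow(find_local_maxima(matrix(0, 10, 10), 3)), 0L)

  one <- matrix(0, 9, 9); one[4, 6] <- 2
  got <- find_local_maxima(one, 2)
  expect_equal(got, data.frame(row = 4L, col = 6L, score = 2))

  set.seed(12)
  for (rep in 1:8) {
    x <- matrix(pmax(0, rnorm(24 * 24)), 24, 24)
    d <- sample(2:5, 1)
    expect_identical(find_local_maxima(x, d), oracle_maxima(x, d))
  }
  expect_error(find_local_maxima(matrix(1, 3, 3), 0), ">= 1")
})

test_that("radial segmentation recovers a disc footprint and drops flat peaks", {
  n <- 101
  x <- matrix(1000, n, n)
  x[disc_mask(n, 10)] <- 1400
  cfg <- prefilter_config(segment_radius_px = 30, min_area_px = 50,
                          max_area_px = 2000)
  peaks <- data.frame(row = 51L, col = 51L, score = 1)
  cands <- radial_segment(x, peaks, cfg)
  expect_length(cands, 1L)
  expect_lt(abs(cands[[1]]$area_px - pi * 100) / (pi * 100), 0.15)
  expect_equal(unname(cands[[1]]$center), c(51, 51), tolerance = 1)

  # perfectly flat image: the boundary collapses, no candidate survives
  expect_length(radial_segment(matrix(1000, n, n), peaks, cfg), 0L)
  expect_error(radial_segment(x, data.frame(row = 999L, col = 1L, score = 1),
                              cfg), "outside")
})

test_that("two nearby discs segment into disjoint masks, one per peak", {
  n <- 121
  x <- matrix(1000, n, n)
  x[disc_mask(n, 9, 45, 45)] <- 1500
  x[disc_mask(n, 9, 45, 75)] <- 1500
  cfg <- prefilter_config(segment_radius_px = 25, min_area_px = 50,
                          max_area_px = 2000)
  peaks <- data.frame(row = c(45L, 45L), col = c(45L, 75L), score = c(1, 1))
  cands <- radial_segment(x, peaks, cfg)
  expect_length(cands, 2L)
  # rebuild full-image masks from crops and check disjointness
  full <- lapply(cands, function(cd) {
    m <- matrix(FALSE, n, n)
    rr <- cd$bbox[["row"]] + seq_len(nrow(cd$mask)) - 1L
    cc <- cd$bbox[["col"]] + seq_len(ncol(cd$mask)) - 1L
    m[rr, cc] <- cd$mask
    m
  })
  expect_equal(sum(full[[1]] & full[[2]]), 0L)
})

test_that("candidate invariants hold on a synthetic cell tile", {
  sc <- render_tile(scene_config(densities = c(CART = 8), crowding = 70),
                    seed = 501)
  cfg <- prefilter_config()
  cands <- detect_candidates(sc$image, cfg)
  expect_gt(length(cands), 0L)
  for (cd in cands) {
    expect_gt(cd$peak_score, 0)
    expect_gte(cd$area_px, cfg$min_area_px)
    expect_lte(cd$area_px, cfg$max_area_px)
    expect_equal(sum(cd$mask), cd$area_px)
    expect_equal(dim(cd$mask), dim(cd$crop))
  }
})

test_that("detection is translation-equivariant up to a pixel", {
  sc <- render_tile(scene_config(
    geometry = imaging_geometry(view_px = c(320L, 320L)),
    densities = c(CART = 3), crowding = 90), seed = 502)
  x <- sc$image$pixels
  dr <- 7L; dc <- 5L
  a <- x[1:256, 1:256]
  b <- x[(1 + dr):(256 + dr), (1 + dc):(256 + dc)]
  ca <- detect_candidates(a)
  cb <- detect_candidates(b)
  expect_gt(length(ca), 0L)
  expect_equal(length(ca), length(cb))
  ctra <- t(vapply(ca, function(c) c$center, c(row = 0, col = 0)))
  ctrb <- t(vapply(cb, function(c) c$center, c(row = 0, col = 0)))
  ctra <- ctra[order(ctra[, 1], ctra[, 2]), , drop = FALSE]
  ctrb <- ctrb[order(ctrb[, 1], ctrb[, 2]), , drop = FALSE]
  expect_true(all(abs((ctra - ctrb) -
                        matrix(c(dr, dc), nrow(ctra), 2, byrow = TRUE)) <= 1))
})

test_that("contrast polarity does not change the detected count", {
  cfgs <- scene_config(densities = c(CART = 10), crowding = 70)
  cfgd <- scene_config(densities = c(CART = 10), crowding = 70,
                       contrast_polarity = "dark_center")
  bright <- render_tile(cfgs, seed = 503)
  dark <- render_tile(cfgd, seed = 503)
  expect_equal(bright$truth[, c("row", "col")], dark$truth[, c("row", "col")])
  expect_equal(length(detect_candidates(bright$image)),
               length(detect_candidates(dark$image)))
  expect_gte(truth_recall(detect_candidates(dark$image), dark$truth), 0.9)
})

test_that("pure-noise tiles produce at most one false candidate", {
  for (s in 1:3) {
    bl <- render_tile(scene_config(densities = c(CART = 0)), seed = 600 + s)
    expect_lte(length(detect_candidates(bl$image)), 1L)
  }
})

test_that("raising crowding never raises per-object recall", {
  sparse <- render_tile(scene_config(densities = c(CART = 8), crowding = 80),
                        seed = 504)
  dense <- render_tile(scene_config(densities = c(CART = 40), crowding = 0),
                       seed = 504)
  rec_sparse <- truth_recall(detect_candidates(sparse$image), sparse$truth)
  rec_dense <- truth_recall(detect_candidates(dense$image), dense$truth)
  expect_gte(rec_sparse + 0.02, rec_dense)
})
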