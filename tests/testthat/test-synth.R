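test_that("tile rendering is deterministic under a fixed seed", {
  a <- render_tile(scene_config(densities = c(CART = 20)), seed = 99)
  b <- render_tile(scene_config(densities = c(CART = 20)), seed = 99)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  c <- render_tile(scene_config(densities = c(CART = 20)), seed = 100)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("zero densities give a pure-noise tile with empty truth", {
  sc <- render_tile(scene_config(densities = c(CART = 0)), seed = 1)
  expect_equal(nrow(sc$truth), 0L)
  px <- sc$image$pixels
  expect_lt(abs(mean(px) - 10000), 50)
  expect_lt(abs(sd(px) - 100), 10)
})

test_that("object counts are Poisson at the configured density", {
  cfg <- scene_config(geometry = imaging_geometry(view_px = c(192L, 192L)),
                      densities = c(CART = 20), crowding = 0,
                      cell_diameter_um_range = c(7, 10))
  counts <- vapply(1:200, function(s)
    nrow(render_tile(cfg, seed = 1000 + s)$truth), 0L)
  # mean 20, SE sqrt(20/200) ~ 0.32; allow 3 SE
  expect_lt(abs(mean(counts) - 20), 1)
  expect_gt(var(counts), 10)  # dispersion consistent with Poisson, not fixed
})

test_that("truth records coincide with rendered contrast extrema", {
  sc <- render_tile(scene_config(densities = c(CART = 6), crowding = 80),
                    seed = 77)
  px <- sc$image$pixels
  for (i in seq_len(nrow(sc$truth))) {
    r0 <- round(sc$truth$row[i]); c0 <- round(sc$truth$col[i])
    centre <- mean(px[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)])
    expect_gt(abs(centre - 10000), 400)  # well above noise at the center
  }
})

test_that("placement honors the crowding constraint or fails loudly", {
  sc <- render_tile(scene_config(densities = c(CART = 12), crowding = 60),
                    seed = 3)
  tr <- sc$truth
  if (nrow(tr) > 1) {
    d <- as.matrix(dist(tr[, c("row", "col")]))
    expect_gte(min(d[upper.tri(d)]), 60)
  }
  expect_error(
    render_tile(scene_config(
      geometry = imaging_geometry(view_px = c(256L, 256L)),
      densities = c(CART = 200), crowding = 100), seed = 4),
    "placement")
})

test_that("fluorescence rendering separates positives from negatives", {
  sc <- render_tile(scene_config(densities = c(CART = 12), crowding = 70),
                    seed = 55)
  fl <- render_fluor(sc$truth, dims = dim(sc$image$pixels),
                     positive_fraction = 0.5, seed = 56)
  rois <- data.frame(image = "f", x_px = sc$truth$col, y_px = sc$truth$row,
                     radius_px = sc$truth$radius_px, label = "CART")
  recs <- pair_rois(rois, fl$image)
  pos <- recs$stat[fl$positive]
  neg <- recs$stat[!fl$positive]
  if (length(pos) && length(neg)) {
    pairs <- outer(pos, neg, ">")
    expect_gte(mean(pairs), 0.95)
  }
  none <- render_fluor(sc$truth, dims = dim(sc$image$pixels),
                       positive_fraction = 0, seed = 57)
  expect_false(any(none$positive))
  # no dots: intensities stay near background + autofluorescence
  expect_lt(max(none$image$pixels), 500 + 150 + 200)
})

test_that("the positive fraction concentrates at its binomial expectation", {
  truth <- data.frame(class = "CART",
                      row = runif(1000, 30, 480), col = runif(1000, 30, 480),
                      radius_px = 15, contrast = 800)
  fl <- render_fluor(truth, dims = c(512L, 512L), positive_fraction = 0.88,
                     seed = 58)
  expect_lt(abs(mean(fl$positive) - 0.88), 0.03)
})

test_that("object library bookkeeping yields disjoint train/test partitions", {
  lib <- make_object_library(n_per_class = 10, split = c(5, 5), seed = 8)
  expect_equal(nrow(lib$train$features), 20L)
  expect_equal(nrow(lib$test$features), 20L)
  expect_length(intersect(lib$train$ids, lib$test$ids), 0L)
  expect_equal(unname(table(lib$train$labels)), rep(5L, 4L),
               ignore_attr = TRUE)
  expect_identical(colnames(lib$train$features), feature_names())
  expect_error(make_object_library(n_per_class = 10, split = c(4, 5)),
               "sum")
})

test_that("calibration simulation obeys its capture arithmetic", {
  cfg <- cal_sim_config(concentrations = 10, replicates = 500,
                        capture_efficiency = 1, background_mean = 0)
  tab <- simulate_calibration(cfg, seed = 60)
  obs <- tab$observed[tab$concentration > 0]
  expect_equal(length(obs), 500L)
  # Poisson mean 10 * 7.1 = 71, SE sqrt(71/500) ~ 0.38; allow ~3 SE
  expect_lt(abs(mean(obs) - 71), 1.2)

  blood <- simulate_calibration(cal_sim_config(preset = "blood"), seed = 61)
  blanks <- blood$observed[blood$concentration == 0]
  expect_gt(mean(blanks), 100)  # high-background blank regime

  silent <- simulate_calibration(
    cal_sim_config(concentrations = 1, replicates = 5,
                   capture_efficiency = 1e-6, effective_volume_ul = 1e-3,
                   background_mean = 0), seed = 62)
  expect_true(all(silent$observed == 0))
})

test_that("simulated calibrations are recovered by the matching fit form", {
  # linear capture, no background: power fit recovers slope ~ eff * volume
  set.seed(63)
  b_hat <- a_hat <- numeric(10)
  for (s in 1:10) {
    tab <- simulate_calibration(cal_sim_config(seed = 70 + s))
    cal <- tab[tab$concentration > 0, ]
    f <- fit_power(cal$concentration, pmax(cal$observed, 1))
    a_hat[s] <- f$a; b_hat[s] <- f$b
  }
  expect_lt(abs(median(b_hat) - 1), 0.08)
  expect_lt(abs(median(a_hat) - 0.9 * 7.1) / (0.9 * 7.1), 0.25)

  # saturating blood response: the log fit attains R^2 > 0.9 in most seeds
  r2 <- vapply(1:10, function(s) {
    tab <- simulate_calibration(cal_sim_config(preset = "blood",
                                               seed = 80 + s))
    cal <- tab[tab$concentration > 0, ]
    fit_log(cal$concentration, cal$observed)$r_squared
  }, 0)
  expect_gte(mean(r2 > 0.9), 0.8)
})
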