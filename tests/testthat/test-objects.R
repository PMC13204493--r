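test_that("a digital disc mask yields circularity near 1 and zero intensity SD", {
  cand <- make_mask_candidate(disc_mask(31, 12))
  f <- extract_features(cand)
  expect_lt(abs(f[["circularity"]] - 1), 0.1)
  expect_equal(f[["sd_intensity"]], 0)
  expect_equal(f[["area_px"]], sum(disc_mask(31, 12)))
  expect_equal(f[["equivalent_radius_px"]], sqrt(f[["area_px"]] / pi))
  expect_lt(f[["eccentricity"]], 0.3)
})

test_that("a 2:1 elongated mask has high eccentricity", {
  n <- 41
  rho <- outer((1:n - 21)^2 / 16^2, (1:n - 21)^2 / 8^2, "+")
  cand <- make_mask_candidate(rho <= 1)
  expect_gt(extract_features(cand)[["eccentricity"]], 0.8)
})

test_that("intensity statistics equal their sort-based oracles", {
  set.seed(20)
  mask <- disc_mask(21, 8)
  crop <- matrix(runif(21 * 21, 0, 4000), 21, 21)
  f <- extract_features(make_mask_candidate(mask, crop))
  v <- sort(crop[mask])
  expect_equal(f[["median_intensity"]], v[(length(v) + 1) %/% 2])
  expect_equal(f[["min_intensity"]], v[1])
  expect_equal(f[["max_intensity"]], v[length(v)])
  expect_equal(f[["mean_intensity"]], mean(v))
  expect_equal(f[["sd_intensity"]], sqrt(mean((v - mean(v))^2)))
  expect_equal(f[["q50_intensity"]], unname(stats::quantile(v, 0.5)))
})

test_that("feature extraction rejects empty masks and keeps the frozen order", {
  expect_error(extract_features(make_mask_candidate(matrix(FALSE, 5, 5))),
               "empty mask")
  f <- extract_features(make_mask_candidate(disc_mask(15, 5)))
  expect_identical(names(f), feature_names())
  expect_length(f, 16L)
})

test_that("training is deterministic under a fixed seed and validates input", {
  set.seed(21)
  n <- 40
  X <- rbind(matrix(rnorm(n * 16, 0), n, 16), matrix(rnorm(n * 16, 3), n, 16))
  colnames(X) <- feature_names()
  y <- rep(c("CART", "PLATELET"), each = n)
  m1 <- train_classifier(X, y, seed = 7)
  m2 <- train_classifier(X, y, seed = 7)
  expect_identical(predict(m1, X), predict(m2, X))
  expect_error(train_classifier(X, rep("CART", 2 * n)), "2 classes")
  expect_error(train_classifier(X[1:41, ], c(rep("CART", 40), "RBC")),
               "at least 5")
})

test_that("four separable clusters are classified nearly perfectly", {
  set.seed(22)
  centers <- matrix(0, 4, 16)
  for (k in 1:4) centers[k, ] <- rnorm(16, sd = 4)
  gen <- function(n) {
    X <- do.call(rbind, lapply(1:4, function(k)
      sweep(matrix(rnorm(n * 16, sd = 0.5), n, 16), 2, centers[k, ], "+")))
    colnames(X) <- feature_names()
    list(X = X, y = rep(object_classes(), each = n))
  }
  tr <- gen(100); te <- gen(50)
  model <- train_classifier(tr$X, tr$y, seed = 1)
  ev <- evaluate_classifier(model, te$X, te$y)
  expect_gte(ev$accuracy, 0.95)
})

test_that("shuffled labels score at chance level", {
  set.seed(23)
  X <- matrix(rnorm(400 * 16), 400, 16)
  colnames(X) <- feature_names()
  y <- sample(rep(object_classes(), each = 100))
  model <- train_classifier(X[1:200, ], y[1:200], seed = 1)
  ev <- evaluate_classifier(model, X[201:400, ], y[201:400])
  # 4 balanced classes: chance 0.25, binomial SD sqrt(.25*.75/200)
  expect_lt(abs(ev$accuracy - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
})

test_that("classification labels every candidate and conserves counts", {
  model <- local({
    set.seed(24)
    X <- do.call(rbind, lapply(0:3, function(k)
      matrix(rnorm(30 * 16, mean = 3 * k), 30, 16)))
    colnames(X) <- feature_names()
    train_classifier(X, rep(object_classes(), each = 30), seed = 2)
  })
  empty <- classify(model, list())
  expect_equal(sum(empty$counts), 0L)
  expect_named(empty$counts, object_classes())

  set.seed(25)
  cands <- lapply(1:7, function(i) {
    cd <- make_mask_candidate(disc_mask(21, 6),
                              matrix(runif(441, 0, 100), 21, 21))
    cd$features <- extract_features(cd)
    cd
  })
  res <- classify(model, cands)
  expect_equal(sum(res$counts), 7L)
  expect_true(all(vapply(res$candidates, function(c)
    c$label %in% object_classes(), TRUE)))
})

test_that("sensitivity and specificity follow the confusion-matrix formulas", {
  # the assay's operating point: TP 44, FN 6, TN 144, FP 6 on a 50/150 split
  truth <- c(rep("CART", 50), rep("RBC", 150))
  pred <- c(rep("CART", 44), rep("RBC", 6), rep("CART", 6), rep("RBC", 144))
  ev <- eval_report(truth, pred)
  expect_equal(unname(ev$sensitivity["CART"]), 0.88)
  expect_equal(unname(ev$specificity["CART"]), 0.96)
  expect_equal(sum(ev$confusion), ev$n_test)

  perfect <- eval_report(rep(object_classes(), 10), rep(object_classes(), 10))
  expect_equal(unname(perfect$sensitivity), rep(1, 4))
  expect_equal(unname(perfect$specificity), rep(1, 4))

  none <- eval_report(c(rep("CART", 5), rep("OTHER", 5)), rep("OTHER", 10))
  expect_equal(unname(none$sensitivity["CART"]), 0)
  expect_equal(unname(none$specificity["CART"]), 1)
})

test_that("evaluation is invariant to test-set permutation", {
  set.seed(26)
  X <- matrix(rnorm(120 * 16), 120, 16)
  colnames(X) <- feature_names()
  y <- sample(object_classes(), 120, replace = TRUE, prob = c(.4, .2, .2, .2))
  model <- local({
    Xt <- do.call(rbind, lapply(0:3, function(k)
      matrix(rnorm(20 * 16, mean = k), 20, 16)))
    colnames(Xt) <- feature_names()
    train_classifier(Xt, rep(object_classes(), each = 20), seed = 3)
  })
  e1 <- evaluate_classifier(model, X, y)
  perm <- sample(120)
  e2 <- evaluate_classifier(model, X[perm, ], y[perm])
  expect_equal(e1$confusion, e2$confusion)
  expect_equal(e1$sensitivity, e2$sensitivity)
})

test_that("a saved and reloaded model predicts identically", {
  set.seed(27)
  X <- do.call(rbind, lapply(0:3, function(k)
    matrix(rnorm(25 * 16, mean = 2 * k), 25, 16)))
  colnames(X) <- feature_names()
  model <- train_classifier(X, rep(object_classes(), each = 25), seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  Xnew <- matrix(rnorm(40 * 16, mean = 3), 40, 16)
  expect_identical(predict(model, Xnew), predict(back, Xnew))
  expect_error(predict(model, Xnew[, 1:10]), "mismatch")
})
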