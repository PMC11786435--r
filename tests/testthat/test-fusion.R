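test_that("extracted pooled features have the stage-4 concat width", {
  sh <- forward_shapes(build_swnet())
  expect_equal(sh[sh$name == "gap", "channels"], 1024)
  m <- swnet_model(desk_graph(), seed = 14)
  ds <- fixture_dataset("featsm", synthetic_spec(
    n_images = 6, image_size = DESK_SIZE, seed = 81))
  f <- extract_features(m, ds$manifest)
  expect_equal(dim(f), c(6, 128))  # 4 x (256/8) channels at width 1/8
  expect_true(all(is.finite(f)))
  # determinism: identical inputs give identical vectors
  f2 <- extract_features(m, ds$manifest)
  expect_identical(unclass(f), unclass(f2))
  expect_error(extract_features(m, ds$manifest, layer = "blah"),
               "unknown layer")
})

test_that("fusion concatenates with exact provenance round-trip", {
  set.seed(15)
  a <- matrix(rnorm(5 * 1024), 5, 1024)
  b <- matrix(rnorm(5 * 1024), 5, 1024)
  c3 <- matrix(rnorm(5 * 128), 5, 128)
  fused2 <- fuse_concat(list(a, b))
  expect_equal(ncol(fused2), 2048)
  fused1 <- fuse_concat(list(a))
  expect_equal(unclass(fused1)[, ], a)
  fused3 <- fuse_concat(list(a, b, c3))
  expect_equal(ncol(fused3), 2176)
  prov <- attr(fused3, "provenance")
  expect_equal(nrow(prov), 3)
  expect_equal(prov$offset, c(0L, 1024L, 2048L))
  expect_equal(sum(prov$length), ncol(fused3))
  # round-trip each component
  expect_equal(fused_component(fused3, 1), a)
  expect_equal(fused_component(fused3, 2), b)
  expect_equal(fused_component(fused3, 3), c3)
  expect_error(fuse_concat(list(a, b[1:3, ])), "misaligned")
})

test_that("merging manifests conserves records and class totals", {
  dsA <- bias_data("srcA")
  dsB <- bias_data("srcB")
  suppressMessages(pooled <- merge_datasets(list(dsA$manifest,
                                                 dsB$manifest)))
  expect_equal(nrow(pooled), 240)
  expect_equal(sum(pooled$label == "malignant"),
               sum(dsA$manifest$label == "malignant") +
                 sum(dsB$manifest$label == "malignant"))
  expect_setequal(unique(pooled$source_dataset), c("srcA", "srcB"))
  expect_identical(merge_datasets(list(dsA$manifest)), dsA$manifest)
  # duplicated paths across sources are kept with a warning
  dup <- dsA$manifest
  dup$source_dataset <- "copyA"
  expect_warning(suppressMessages(both <- merge_datasets(
    list(dsA$manifest, dup))), "duplicate")
  expect_equal(nrow(both), 240)
})

test_that("softmax head separates Gaussian clusters like a centroid oracle", {
  set.seed(16)
  d <- 20
  mu <- rep(c(2, -2), each = d / 2)
  make <- function(n) {
    y <- rep(c("benign", "malignant"), each = n / 2)
    X <- t(vapply(seq_len(n), function(i) {
      s <- if (y[i] == "malignant") mu else -mu
      s + rnorm(d)
    }, numeric(d)))
    list(X = X, y = y)
  }
  tr <- make(120); te <- make(60)
  clf <- train_fused_classifier(tr$X, tr$y, te$X, te$y)
  expect_gte(clf$metrics$accuracy, 0.95)
  # independent nearest-centroid oracle
  cb <- colMeans(tr$X[tr$y == "benign", ])
  cm <- colMeans(tr$X[tr$y == "malignant", ])
  oracle <- apply(te$X, 1, function(v) {
    if (sum((v - cm)^2) < sum((v - cb)^2)) "malignant" else "benign"
  })
  expect_gte(mean(oracle == te$y), 0.95)
  expect_equal(clf$predict(te$X), unname(oracle))
})

test_that("label-shuffled features score at chance", {
  set.seed(17)
  X <- matrix(rnorm(200 * 30), 200, 30)
  y <- sample(rep(c("benign", "malignant"), each = 100))
  Xte <- matrix(rnorm(100 * 30), 100, 30)
  yte <- sample(rep(c("benign", "malignant"), each = 50))
  clf <- train_fused_classifier(X, y, Xte, yte)
  expect_lt(abs(clf$metrics$accuracy - 0.5), 3 * sqrt(0.25 / 100))
})

test_that("duplicating a feature block leaves accuracy unchanged", {
  set.seed(18)
  d <- 10
  X <- matrix(rnorm(100 * d), 100, d)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(100, sd = 0.4) > 0,
              "malignant", "benign")
  Xte <- matrix(rnorm(60 * d), 60, d)
  yte <- ifelse(Xte[, 1] + 0.5 * Xte[, 2] > 0, "malignant", "benign")
  single <- train_fused_classifier(X, y, Xte, yte)
  doubled <- train_fused_classifier(fuse_concat(list(X, X)), y,
                                    fuse_concat(list(Xte, Xte)), yte)
  expect_equal(doubled$metrics$accuracy, single$metrics$accuracy)
})

test_that("single-class labels are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_fused_classifier(X, rep("benign", 10)), "both classes")
})

test_that("pooling de-confounded sources removes the shortcut penalty", {
  dsT <- bias_data("clean_test")
  mA <- fixture_model("confounded")
  mB <- fixture_model("sourceB")
  mP <- fixture_model("pooled")
  bal_acc <- function(m) {
    cm <- evaluate(m, dsT$manifest)
    (recall(cm) + specificity(cm)) / 2
  }
  accA <- bal_acc(mA); accB <- bal_acc(mB); accP <- bal_acc(mP)
  # the source whose artifact aligns with the lesion-darkness cue adopts
  # the shortcut and pays for it on clean data; pooling repairs that
  expect_gt(accP, accA)
  # the anti-aligned source never adopts its shortcut (it contradicts the
  # morphology cue), so the pooled model can only match it: within one
  # misclassified image on this test set
  expect_gte(accP, accB - 1 / nrow(dsT$manifest))
  # and the pooled model is strictly the least vignette-reliant of the three
  massA <- mean_vignette_mass(mA)
  massB <- mean_vignette_mass(mB)
  massP <- mean_vignette_mass(mP)
  expect_lt(massP, massA)
  expect_lt(massP, massB)
})

test_that("fused deep features from both sources classify the clean test set", {
  dsT <- bias_data("clean_test")
  mA <- fixture_model("confounded")
  mB <- fixture_model("sourceB")
  suppressMessages({
    pooled_train <- merge_datasets(list(bias_data("srcA")$manifest,
                                        bias_data("srcB")$manifest))
  })
  fuse_of <- function(man) {
    fuse_concat(list(extract_features(mA, man), extract_features(mB, man)))
  }
  ftr <- fuse_of(pooled_train)
  fte <- fuse_of(dsT$manifest)
  expect_equal(ncol(ftr), 2 * 128)
  clf <- train_fused_classifier(ftr, pooled_train$label, fte,
                                dsT$manifest$label)
  expect_gte(clf$metrics$accuracy, 0.8)
})
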