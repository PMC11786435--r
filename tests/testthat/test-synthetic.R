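small_spec <- function(...) synthetic_spec(image_size = 32, ...)

test_that("generator honors counts and deterministic class allocation", {
  ds <- fixture_dataset("count100",
                        small_spec(n_images = 100, seed = 31))
  expect_equal(nrow(ds$metadata), 100)
  expect_equal(sum(ds$metadata$label == "malignant"), 50)
  expect_true(all(file.exists(ds$manifest$image_path)))

  ds2 <- fixture_dataset("count30",
                         small_spec(n_images = 30, class_balance = 0.3,
                                    seed = 32))
  expect_equal(sum(ds2$metadata$label == "malignant"), 9)
})

test_that("identical spec and seed reproduce the dataset byte for byte", {
  spec <- small_spec(n_images = 8, seed = 33,
                     vignette_prob = c(benign = 0.5, malignant = 0.5),
                     hair_prob = c(benign = 0.5, malignant = 0.5))
  d1 <- generate_dataset(spec, tempfile("gen1"))
  d2 <- generate_dataset(spec, tempfile("gen2"))
  h1 <- unname(tools::md5sum(d1$manifest$image_path))
  h2 <- unname(tools::md5sum(d2$manifest$image_path))
  expect_identical(h1, h2)
  expect_identical(d1$metadata[-1], d2$metadata[-1])
})

test_that("invalid specs are configuration errors", {
  expect_error(synthetic_spec(n_images = 0), "positive")
  expect_error(synthetic_spec(class_balance = 1.5), "probabilities")
  expect_error(synthetic_spec(vignette_prob = c(-0.1, 0.5)), "probabilities")
  expect_error(
    synthetic_spec(malignant = list(irregularity = c(0.1, 0.2),
                                    variegation = c(1, 2),
                                    diameter_frac = c(0.5, 1.2),
                                    color = c(0.3, 0.2, 0.1))),
    "smaller than the image")
})

test_that("vignette darkens the periphery and only the periphery", {
  set.seed(40)
  img <- array(runif(64 * 64 * 3, min = 0.3, max = 0.9), dim = c(64, 64, 3))
  out <- add_vignette(img, 1.0)
  # corners darkened, center untouched
  expect_lt(out[1, 1, 1], img[1, 1, 1])
  expect_lt(out[64, 64, 2], img[64, 64, 2])
  ctr <- 32
  expect_equal(out[ctr, ctr, ], img[ctr, ctr, ])
  expect_lt(mean(out), mean(img))  # strictly decreases brightness

  out2 <- add_vignette(img, 0.5)
  expect_equal(out2[ctr, ctr, ], img[ctr, ctr, ])
  expect_lt(mean(out2), mean(out))  # smaller clear disc darkens more

  expect_error(add_vignette(img, 0), "0, 1")
  expect_error(add_vignette(img, 1.2), "0, 1")
  expect_error(add_vignette(array(0, dim = c(4, 6, 3))), "square")
})

test_that("vignette mask matches the darkened region", {
  mask <- vignette_mask(64, 0.7)
  img <- array(0.8, dim = c(64, 64, 3))
  out <- add_vignette(img, 0.7)
  changed <- out[, , 1] < img[, , 1] - 1e-12
  expect_false(any(changed & !mask))  # darkening confined to the mask
  expect_gt(mean(changed[mask]), 0.5)  # and covers most of it
})

test_that("hair strokes are dark, seeded and optional", {
  canvas <- array(1, dim = c(128, 128, 3))
  expect_identical(add_hair(canvas, 0), canvas)
  out <- add_hair(canvas, 20, seed = 77)
  expect_identical(out, add_hair(canvas, 20, seed = 77))
  dark <- out[, , 1] < 0.5
  expect_gt(sum(dark), 0)
  # every stroke leaves at least one connected dark component
  n_comp <- max(EBImage::bwlabel(dark))
  expect_gte(n_comp, 20)
})

test_that("metadata flags reflect the rendered confounds", {
  ds <- fixture_dataset("flags",
                        small_spec(n_images = 40, seed = 34,
                                   vignette_prob = c(benign = 1,
                                                     malignant = 1)))
  expect_true(all(ds$metadata$has_vignette))
  # a vignetted image is darker at the corner than at the center
  img <- png::readPNG(ds$manifest$image_path[1])
  expect_lt(mean(img[1:2, 1:2, ]), mean(img[15:18, 15:18, ]))
})

test_that("phi coefficient matches hand-computed contingency cases", {
  md <- data.frame(label = rep(c("malignant", "benign"), each = 20),
                   has_vignette = rep(c(TRUE, FALSE), each = 20))
  expect_equal(confound_association(md), 1.0)

  md$has_vignette <- rep(c(TRUE, FALSE), 20)
  expect_equal(confound_association(md),
               with(list(
                 n11 = sum(md$label == "malignant" & md$has_vignette),
                 n10 = sum(md$label == "malignant" & !md$has_vignette),
                 n01 = sum(md$label == "benign" & md$has_vignette),
                 n00 = sum(md$label == "benign" & !md$has_vignette)),
                 (n11 * n00 - n10 * n01) /
                   sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))))

  md$has_vignette <- TRUE
  expect_warning(phi <- confound_association(md), "degenerate")
  expect_equal(phi, 0)
})

test_that("independent confound assignment gives phi near zero", {
  ds <- fixture_dataset("indep",
                        synthetic_spec(n_images = 1500, image_size = 16,
                                       vignette_prob = c(benign = 0.5,
                                                         malignant = 0.5),
                                       seed = 35))
  expect_lt(abs(confound_association(ds$metadata)), 3 / sqrt(1500))
})

test_that("the confound dial tracks requested per-class probabilities", {
  # p(v|mal)=0.9, p(v|ben)=0.1, balanced classes: expected phi = 0.8
  for (seed in c(41, 42, 43)) {
    ds <- fixture_dataset(paste0("dial", seed),
                          synthetic_spec(n_images = 400, image_size = 16,
                                         vignette_prob = c(benign = 0.1,
                                                           malignant = 0.9),
                                         seed = seed))
    expect_lt(abs(confound_association(ds$metadata) - 0.8), 3 / sqrt(400))
  }
})

test_that("morphology parameters alone classify the labels perfectly", {
  spec <- small_spec(n_images = 120, seed = 36)
  ds <- fixture_dataset("morph", spec)
  preds <- morphology_classifier(ds$metadata, spec)
  expect_equal(mean(preds == ds$metadata$label), 1.0)
})
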