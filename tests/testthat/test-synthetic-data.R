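test_that("phantom generation is seeded, sized and optionally written", {
  sp <- phantom_spec(image_size = 16L, seed = 42L)
  a <- generate_phantoms(5, sp)
  b <- generate_phantoms(5, sp)
  expect_equal(dim(a$images), c(16, 16, 5))
  expect_identical(a$images, b$images)
  expect_true(all(a$images >= 0 & a$images <= 255))
  td <- withr::local_tempdir()
  out <- generate_phantoms(3, sp, out_dir = td)
  expect_length(list.files(td, pattern = "phantom_.*\\.png$"), 3L)
  expect_true(file.exists(file.path(td, "manifest.csv")))
})

test_that("noise-free single-shell phantom is piecewise constant", {
  sp <- phantom_spec(image_size = 32L, n_shells = 1L, noise_sd = 0,
                     deformation = 0, seed = 1L)
  img <- generate_phantoms(1, sp)$images[, , 1]
  expect_equal(length(unique(as.numeric(img))), 2L)
})

test_that("lesion dataset has the stated class imbalance and determinism", {
  les <- generate_lesion_dataset(seed = 9L)
  expect_equal(dim(les$images)[3], 325L)
  expect_equal(sum(les$labels == "malignant"), 75L)
  expect_equal(sum(les$labels == "benign"), 250L)
  expect_equal(dim(les$images)[1:2], c(35L, 35L))
  les2 <- generate_lesion_dataset(seed = 9L)
  expect_identical(les$images, les2$images)
  expect_true(all(les$centers >= 1 & les$centers <= 35))
  # manifest coordinates are 0-based
  expect_equal(les$manifest$center_row, les$centers[, 1] - 1L)
})

test_that("zero separability yields chance-level class discrimination", {
  les <- generate_lesion_dataset(100L, 100L, seed = 33L, separability = 0)
  sp <- split_dataset(les$labels, 0.5, seed = 44L)
  m <- train_eval_classifier(les$images[, , sp$train], les$labels[sp$train])
  p <- predict_eval_prob(m, les$images[, , sp$test])
  y <- les$labels[sp$test] == "malignant"
  auc <- mean(outer(p[y], p[!y], `>`)) + 0.5 * mean(outer(p[y], p[!y], `==`))
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})

test_that("volume slicing preserves order and round-trips", {
  v <- array(seq_len(4 * 5 * 3), c(4, 5, 3))
  sl <- slice_volume(v)
  expect_length(sl, 3L)
  expect_equal(sl[[2]], v[, , 2])
  expect_equal(simplify2array(sl), v)
  expect_error(slice_volume(matrix(1, 2, 2)), "3-D")
  expect_error(slice_volume(array(1, c(2, 2, 0))), "empty")
})

test_that("ROI crop centres the lesion and reflect-pads at borders", {
  set.seed(5)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  patch <- roi_crop(img, c(30L, 40L), side = 35L)
  expect_equal(dim(patch), c(35L, 35L))
  expect_equal(patch[18, 18], img[30, 40])    # centre pixel preserved
  corner <- roi_crop(img, c(1L, 1L), side = 35L)
  expect_equal(dim(corner), c(35L, 35L))
  expect_equal(corner[18, 18], img[1, 1])
  # reflection: one step above row 1 mirrors row 2
  expect_equal(corner[17, 18], img[2, 1])
  expect_error(roi_crop(img, c(100L, 1L)), "bounds")
  expect_error(roi_crop(matrix(1, 10, 10), c(5L, 5L), side = 35L), "side")
})

test_that("augmentation produces k seeded randomised copies of equal size", {
  set.seed(10)
  img <- generate_phantoms(1, phantom_spec(image_size = 32L, seed = 2L))$images[, , 1]
  cfg <- augmentation_config(seed = 3L)
  set.seed(cfg$seed)
  a <- augment(img, cfg, k = 10L)
  expect_equal(dim(a), c(32, 32, 10))
  set.seed(cfg$seed)
  b <- augment(img, cfg, k = 10L)
  expect_identical(a, b)
  expect_false(identical(a[, , 1], a[, , 2]))
  # zero-magnitude config is the identity
  id_cfg <- augmentation_config(rotation = 0, translation = 0,
                                scale = c(1, 1), crop_jitter = 0, noise_sd = 0)
  ident <- augment(img, id_cfg, k = 3L)
  for (j in 1:3) expect_equal(ident[, , j], img)
})

test_that("expansion count law n*(k+1) holds with originals first", {
  imgs <- generate_phantoms(4, phantom_spec(image_size = 16L, seed = 6L))$images
  cfg <- augmentation_config(seed = 8L)
  for (k in c(0L, 2L, 5L)) {
    out <- expand_with_originals(imgs, cfg, k = k)
    expect_equal(dim(out)[3], 4L * (k + 1L))
    expect_equal(out[, , 1:4], imgs)
  }
  o1 <- expand_with_originals(imgs, cfg, k = 3L)
  o2 <- expand_with_originals(imgs, cfg, k = 3L)
  expect_identical(o1, o2)
})

test_that("stratified split is proportional, disjoint and exhaustive", {
  labs <- rep(c("a", "b"), c(75, 250))
  sp <- split_dataset(labs, 0.8, seed = 1L)
  expect_equal(sum(labs[sp$train] == "a"), 60L)
  expect_equal(sum(labs[sp$train] == "b"), 200L)
  expect_length(sp$test, 65L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labs))
  # 2-per-class toy set at fraction 0.5
  sp2 <- split_dataset(c("x", "x", "y", "y"), 0.5, seed = 2L)
  expect_length(sp2$train, 2L)
  expect_error(split_dataset(c("x", "y", "y"), 0.5), "fewer than 2")
  # class ratio preserved within rounding for other fractions
  sp3 <- split_dataset(labs, 0.6, seed = 3L)
  expect_equal(sum(labs[sp3$train] == "a"), 45L)
  expect_equal(sum(labs[sp3$train] == "b"), 150L)
})
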