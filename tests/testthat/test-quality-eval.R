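test_that("HOG descriptor has fixed length, zero response on flat images", {
  fp <- feature_params()
  flat <- matrix(128, 64, 64)
  h <- hog_features(flat, fp)
  expect_true(all(h == 0))
  set.seed(1)
  lens <- vapply(1:5, function(i)
    length(hog_features(matrix(runif(64 * 64, 0, 255), 64, 64), fp)),
    numeric(1))
  expect_true(all(lens == lens[1]))
  expect_equal(lens[1], 7 * 7 * 2 * 2 * 9)   # 8x8 cells, 2x2 blocks, 9 bins
  expect_error(hog_features(matrix(1, 4, 4), fp), "smaller than one cell")
})

test_that("a vertical edge concentrates mass in the horizontal-gradient bin", {
  img <- matrix(0, 64, 64)
  img[, 33:64] <- 255                        # step across columns
  h <- hog_features(img)
  # block layout: (cell within block, orientation, block)
  h3 <- array(h, c(4, 9, length(h) / 36))
  bin_mass <- apply(h3, 2, sum)
  expect_equal(which.max(bin_mass), 1L)      # angle 0 = pure horizontal gradient
  expect_gt(bin_mass[1], 0.99 * sum(bin_mass))
})

test_that("LBP histogram is normalised, gray-shift invariant, flat-aware", {
  set.seed(2)
  img <- matrix(runif(35 * 35, 50, 200), 35, 35)
  l <- lbp_features(img)
  expect_length(l, 10L)
  expect_equal(sum(l), 1)
  expect_equal(lbp_features(img + 10), l)    # monotone intensity shift
  flat <- matrix(77, 20, 20)
  lf <- lbp_features(flat)
  expect_equal(lf[9], 1)                     # all-ones (flat) pattern bin
})

test_that("cascade concatenates HOG then LBP with additive lengths", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  h <- hog_features(img); l <- lbp_features(img)
  f <- cascade(h, l)
  expect_length(f, length(h) + length(l))
  expect_equal(as.numeric(f[seq_along(h)]), h)
  expect_equal(as.numeric(f[length(h) + seq_along(l)]), l)
  expect_identical(cascade(h, l), cascade(h, l))
})

test_that("evaluation classifier separates separable classes deterministically", {
  les <- generate_lesion_dataset(40L, 40L, seed = 5L, separability = 1)
  m1 <- train_eval_classifier(les$images, les$labels)
  p1 <- predict_eval_prob(m1, les$images)
  expect_true(all(p1 >= 0 & p1 <= 1))
  acc <- mean((p1 > 0.5) == (les$labels == "malignant"))
  expect_gte(acc, 0.95)
  m2 <- train_eval_classifier(les$images, les$labels)
  expect_identical(p1, predict_eval_prob(m2, les$images))
  expect_error(train_eval_classifier(les$images,
                                     factor(rep("benign", 80),
                                            levels = c("malignant", "benign"))),
               "two classes")
})

test_that("probability distributions are valid and duplication-invariant", {
  les <- generate_lesion_dataset(30L, 30L, seed = 6L)
  m <- train_eval_classifier(les$images, les$labels)
  P <- probability_distribution(m, les$images, n_bins = 10L)
  expect_length(P$p, 10L)
  expect_true(all(P$p > 0))                  # smoothing leaves no empty bin
  expect_equal(sum(P$p), 1, tolerance = 1e-9)
  # duplicating every image leaves the distribution unchanged up to the
  # n-dependent smoothing mass (1/(10n) per bin)
  dup <- les$images[, , rep(seq_len(60), 2)]
  Q <- probability_distribution(m, dup, n_bins = 10L)
  expect_lt(max(abs(P$p - Q$p)), 1e-4)
  expect_error(probability_distribution(m, array(0, c(5, 5, 0))), "empty")
})

test_that("KL divergence matches hand evaluations and is asymmetric", {
  mk <- function(p) list(edges = seq(0, 1, length.out = length(p) + 1), p = p)
  expect_equal(kl_divergence(mk(c(1, 0)), mk(c(0.5, 0.5))), log(2))
  expect_equal(kl_divergence(mk(c(0.5, 0.5)), mk(c(0.25, 0.75))),
               0.5 * log(2) + 0.5 * log(2 / 3))
  P <- mk(c(0.8, 0.2)); Q <- mk(c(0.3, 0.7))
  expect_equal(kl_divergence(P, P), 0)
  expect_false(isTRUE(all.equal(kl_divergence(P, Q), kl_divergence(Q, P))))
  expect_error(kl_divergence(mk(c(1, 0)), mk(c(0.2, 0.3, 0.5))), "binnings")
})

test_that("KL divergence is nonnegative over random distribution pairs", {
  set.seed(7)
  for (k in 1:200) {
    n <- sample(2:20, 1)
    p <- runif(n); p <- p / sum(p)
    q <- runif(n, 0.01, 1); q <- q / sum(q)
    d <- list(edges = seq(0, 1, length.out = n + 1))
    expect_gte(kl_divergence(c(d, list(p = p)), c(d, list(p = q))), 0)
  }
})

test_that("generated-set evaluation enforces counts and scores sanely", {
  les <- generate_lesion_dataset(40L, 40L, seed = 8L)
  m <- train_eval_classifier(les$images, les$labels)
  benign <- les$images[, , les$labels == "benign"]
  a <- benign[, , 1:20]; b <- benign[, , 21:40]
  expect_equal(evaluate_generated(a, a, m), 0)
  expect_error(evaluate_generated(a, benign[, , 1:19], m), "20 real vs 19")
  # ordering invariance
  expect_equal(evaluate_generated(a, b, m),
               evaluate_generated(a, b[, , 20:1], m))
  # structured real vs pure noise scores worse than held-out real
  set.seed(9)
  noise <- array(runif(35 * 35 * 20, 0, 255), c(35, 35, 20))
  expect_gt(evaluate_generated(a, noise, m), evaluate_generated(a, b, m))
})

test_that("same-distribution samples give small, stable KL", {
  ph <- generate_phantoms(1000, phantom_spec(image_size = 16L, seed = 123L))
  m <- phantom_eval_model(ph$images, n_each = 250L, seed = 321L)
  kl <- evaluate_generated(ph$images[, , 251:625], ph$images[, , 626:1000], m)
  expect_lt(kl, 0.05)
})
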