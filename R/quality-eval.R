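# Generated-image quality metric: HOG + LBP texture features, a
# probability-calibrated SVM, binned probability distributions and their
# KL divergence. The score for a generated set is KL(P || Q) where P is the
# binned positive-class-probability histogram of real images and Q that of
# generated images under a classifier trained beforehand on a two-class
# image problem.

#' Feature-extraction parameters for the evaluation pipeline
#'
#' @param orientations Number of unsigned gradient-orientation bins over
#'   `[0, pi)`, default 9.
#' @param cell_size HOG cell side in pixels, default 8.
#' @param block_size HOG block side in cells, default 2 (L2-normalised,
#'   sliding stride one cell).
#' @param lbp_neighbors Number of LBP neighbors (fixed 8-neighborhood).
#' @return List of class `capgan_feature_params`.
#' @export
feature_params <- function(orientations = 9L, cell_size = 8L, block_size = 2L,
                           lbp_neighbors = 8L) {
  stopifnot(orientations >= 2, cell_size >= 2, block_size >= 1,
            lbp_neighbors == 8L)
  structure(list(orientations = as.integer(orientations),
                 cell_size = as.integer(cell_size),
                 block_size = as.integer(block_size),
                 lbp_neighbors = 8L),
            class = "capgan_feature_params")
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Central-difference gradients, unsigned orientation binning over
#' `[0, pi)`, per-cell magnitude-weighted histograms and sliding-block L2
#' normalisation. A constant image yields an all-zero descriptor. The
#' descriptor length is fixed for fixed image geometry and parameters.
#'
#' @param img Grayscale image matrix (file range `[0, 255]`).
#' @param params From [feature_params()].
#' @return Numeric descriptor vector.
#' @export
hog_features <- function(img, params = feature_params()) {
  stopifnot(is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  cs <- params$cell_size
  ncr <- H %/% cs; ncc <- W %/% cs
  if (ncr < 1L || ncc < 1L) stop("hog_features(): image smaller than one cell")
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  nb <- params$orientations
  bin <- pmin(floor(ang / (pi / nb)), nb - 1) + 1
  # crop to whole cells, accumulate magnitude per (cell, orientation)
  rr <- seq_len(ncr * cs); cc <- seq_len(ncc * cs)
  cell_r <- (matrix(rr, length(rr), length(cc)) - 1) %/% cs
  cell_c <- (matrix(cc, length(rr), length(cc), byrow = TRUE) - 1) %/% cs
  key <- cell_r + ncr * cell_c + ncr * ncc * (bin[rr, cc] - 1)
  acc <- rowsum(as.vector(mag[rr, cc]), group = as.vector(key))
  hist3 <- array(0, c(ncr, ncc, nb))
  hist3[as.integer(rownames(acc)) + 1L] <- acc
  bs <- params$block_size
  nbr <- ncr - bs + 1L; nbc <- ncc - bs + 1L
  if (nbr < 1L || nbc < 1L) stop("hog_features(): fewer cells than one block")
  out <- numeric(nbr * nbc * bs * bs * nb)
  blk_len <- bs * bs * nb
  pos <- 0L
  for (bc in seq_len(nbc)) for (br in seq_len(nbr)) {
    v <- as.vector(hist3[br:(br + bs - 1L), bc:(bc + bs - 1L), ])
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    out[pos + seq_len(blk_len)] <- v
    pos <- pos + blk_len
  }
  out
}

#' Uniform rotation-invariant local-binary-pattern histogram
#'
#' Compares each interior pixel to its 8 neighbors (in circular order),
#' maps uniform patterns (at most two 0/1 transitions) to their number of
#' set bits and all non-uniform patterns to a single bin, and returns the
#' normalised 10-bin histogram. Invariant to monotone gray-level shifts.
#'
#' @param img Grayscale image matrix.
#' @param params From [feature_params()] (8 neighbors).
#' @return Numeric vector of length 10 summing to 1.
#' @export
lbp_features <- function(img, params = feature_params()) {
  stopifnot(is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  if (H < 3L || W < 3L) stop("lbp_features(): image too small")
  ctr <- img[2:(H - 1), 2:(W - 1)]
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  bits <- lapply(offs, function(o) {
    img[2:(H - 1) + o[1], 2:(W - 1) + o[2]] >= ctr
  })
  ones <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(seq_along(bits), function(k) {
    nxt <- if (k == length(bits)) 1L else k + 1L
    bits[[k]] != bits[[nxt]]
  }))
  bin <- ifelse(trans <= 2L, ones + 1L, 10L)
  h <- tabulate(bin, nbins = 10L)
  h / sum(h)
}

#' Concatenate HOG and LBP segments
#'
#' Fixed order: HOG first, then LBP.
#'
#' @param hog,lbp Numeric vectors.
#' @return Concatenated feature vector with a `segments` attribute.
#' @export
cascade <- function(hog, lbp) {
  structure(c(hog, lbp), segments = c(hog = length(hog), lbp = length(lbp)))
}

extract_features <- function(images, params) {
  n <- dim(images)[3]
  t(vapply(seq_len(n), function(i) {
    img <- images[, , i]
    as.numeric(cascade(hog_features(img, params), lbp_features(img, params)))
  }, numeric(length(cascade(hog_features(images[, , 1], params),
                            lbp_features(images[, , 1], params))))))
}

#' Train the calibrated evaluation classifier
#'
#' Extracts HOG + LBP features, standardises them, fits a radial-basis SVM
#' (cost 1) and calibrates class probabilities by Platt scaling (a logistic
#' fit to the decision values), which keeps the whole pipeline
#' deterministic. The positive class is the first factor level.
#'
#' @param images Array `(H, W, n)` in file range.
#' @param labels Factor with exactly two levels present.
#' @param params From [feature_params()].
#' @param cost SVM cost parameter, default 1.
#' @return Object of class `capgan_eval_model`.
#' @export
train_eval_classifier <- function(images, labels, params = feature_params(),
                                  cost = 1) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("train_eval_classifier(): need exactly two classes present")
  labels <- droplevels(labels)
  X <- extract_features(images, params)
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- scale(X, center = ctr, scale = scl)
  fit <- e1071::svm(Xs, labels, kernel = "radial", cost = cost,
                    scale = FALSE, probability = FALSE)
  dv <- attr(stats::predict(fit, Xs, decision.values = TRUE), "decision.values")
  pos <- levels(labels)[1]
  # decision.values column is named "level1/level2": positive sign = level1
  y01 <- as.numeric(labels == pos)
  calib <- suppressWarnings(
    stats::glm(y01 ~ dv, family = stats::binomial()))
  structure(list(svm = fit, calib_coef = stats::coef(calib),
                 center = ctr, scale = scl, positive = pos,
                 feature_params = params, levels = levels(labels)),
            class = "capgan_eval_model")
}

#' Positive-class probabilities from the evaluation classifier
#'
#' @param model From [train_eval_classifier()].
#' @param images Array `(H, W, n)` in file range.
#' @return Numeric vector of calibrated probabilities in `[0, 1]`.
#' @export
predict_eval_prob <- function(model, images) {
  X <- extract_features(images, model$feature_params)
  Xs <- scale(X, center = model$center, scale = model$scale)
  dv <- attr(stats::predict(model$svm, Xs, decision.values = TRUE),
             "decision.values")
  as.numeric(stats::plogis(model$calib_coef[1] + model$calib_coef[2] * dv))
}

#' Binned distribution of classifier probabilities
#'
#' Histograms the positive-class probabilities over `n_bins` equal-width
#' bins on `[0, 1]`, adds `1/(10 n)` per bin (n = number of images) to avoid
#' empty bins, and normalises.
#'
#' @param model From [train_eval_classifier()].
#' @param images Array `(H, W, n)`, nonempty.
#' @param n_bins Number of bins, default 10.
#' @return Object of class `capgan_binned_distribution` with `edges`, `p`,
#'   `n`.
#' @export
probability_distribution <- function(model, images, n_bins = 10L) {
  d <- dim(images)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop("probability_distribution(): empty image set")
  pr <- predict_eval_prob(model, images)
  binned_distribution(pr, n_bins, d[3])
}

binned_distribution <- function(probs, n_bins, n) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(probs, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  p <- counts + 1 / (10 * n)
  structure(list(edges = edges, p = p / sum(p), n = n),
            class = "capgan_binned_distribution")
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `sum_i P_i log(P_i / Q_i)` in nats; terms with `P_i = 0` contribute 0.
#' The two distributions must share the same binning.
#'
#' @param P,Q Objects from [probability_distribution()] (or lists with
#'   matching `edges` and probability vector `p`).
#' @return Scalar `>= 0`.
#' @export
kl_divergence <- function(P, Q) {
  if (length(P$edges) != length(Q$edges) ||
      any(abs(P$edges - Q$edges) > 1e-12))
    stop("kl_divergence(): distributions use different binnings")
  i <- P$p > 0
  if (any(Q$p[i] == 0)) stop("kl_divergence(): Q is zero where P has mass")
  sum(P$p[i] * log(P$p[i] / Q$p[i]))
}

#' KL-divergence quality score for generated images
#'
#' Runs equal-sized sets of real and generated images through the trained
#' evaluation classifier, bins the two probability distributions (real = P,
#' generated = Q) and returns `KL(P || Q)`. Lower is better; identical sets
#' score 0.
#'
#' @param real_images,fake_images Arrays `(H, W, n)` with equal `n`.
#' @param model From [train_eval_classifier()].
#' @param n_bins Number of bins, default 10.
#' @return Scalar KL divergence (nats).
#' @export
evaluate_generated <- function(real_images, fake_images, model, n_bins = 10L) {
  nr <- dim(real_images)[3]; nf <- dim(fake_images)[3]
  if (nr != nf)
    stop(sprintf("evaluate_generated(): need equal counts, got %d real vs %d generated",
                 nr, nf))
  P <- probability_distribution(model, real_images, n_bins)
  Q <- probability_distribution(model, fake_images, n_bins)
  kl_divergence(P, Q)
}
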