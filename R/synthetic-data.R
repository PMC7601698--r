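# Synthetic fixtures emulating the study inputs: brain-phantom-like nested
# intensity shells and an imbalanced two-class lesion-patch set, plus the
# standard data-preparation operators (volume slicing, ROI cropping,
# augmentation, expansion, stratified splitting).
#
# All generators are pure functions of (arguments, seed). Images are H x W
# matrices (or H x W x n arrays) in the 8-bit file range [0, 255],
# row = image row.

#' Phantom specification
#'
#' @param image_size Side length, default 64.
#' @param n_shells Number of nested elliptical shells, default 3.
#' @param intensities Shell gray levels, outermost first; defaults spread
#'   over `[60, 200]`. Background is 20.
#' @param noise_sd Additive Gaussian noise standard deviation (gray levels),
#'   default 8.
#' @param deformation Fractional jitter of shell axes/rotation per image,
#'   default 0.1.
#' @param seed RNG seed.
#' @return List of class `capgan_phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, n_shells = 3L, intensities = NULL,
                         noise_sd = 8, deformation = 0.1, seed = 1L) {
  if (is.null(intensities))
    intensities <- round(seq(60, 200, length.out = n_shells))
  stopifnot(n_shells >= 1L, length(intensities) == n_shells,
            all(intensities >= 0 & intensities <= 255), noise_sd >= 0,
            deformation >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_shells = as.integer(n_shells),
                 intensities = intensities, background = 20,
                 noise_sd = noise_sd, deformation = deformation,
                 seed = as.integer(seed)),
            class = "capgan_phantom_spec")
}

draw_phantom <- function(spec) {
  S <- spec$image_size
  def <- spec$deformation
  cy <- S / 2 + stats::runif(1, -def * S / 4, def * S / 4)
  cx <- S / 2 + stats::runif(1, -def * S / 4, def * S / 4)
  theta <- stats::runif(1, 0, pi)
  a0 <- S * 0.42 * (1 + stats::runif(1, -def, def))
  b0 <- S * 0.34 * (1 + stats::runif(1, -def, def))
  yy <- matrix(seq_len(S), S, S) - cy
  xx <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
  u <- cos(theta) * yy + sin(theta) * xx
  w <- -sin(theta) * yy + cos(theta) * xx
  img <- matrix(spec$background, S, S)
  for (k in seq_len(spec$n_shells)) {
    shrink <- 1 - 0.28 * (k - 1)
    inside <- (u / (a0 * shrink))^2 + (w / (b0 * shrink))^2 <= 1
    img[inside] <- spec$intensities[k]
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(S * S, 0, spec$noise_sd), S, S)
  pmin(pmax(img, 0), 255)
}

#' Generate MR-like phantom images
#'
#' Draws `n` grayscale phantoms with nested elliptical intensity shells,
#' per-image geometric jitter and additive Gaussian noise, reproducible per
#' seed. Optionally writes 8-bit PNGs plus a manifest CSV.
#'
#' @param n Number of images, `>= 1`.
#' @param spec From [phantom_spec()].
#' @param out_dir Optional output directory for PNGs and `manifest.csv`.
#' @return List with `images` (array `size x size x n` in `[0, 255]`) and
#'   `manifest` (data frame with `path` when written).
#' @export
generate_phantoms <- function(n, spec = phantom_spec(), out_dir = NULL) {
  stopifnot(n >= 1)
  set.seed(spec$seed)
  S <- spec$image_size
  imgs <- array(0, c(S, S, n))
  for (i in seq_len(n)) imgs[, , i] <- draw_phantom(spec)
  manifest <- data.frame(id = seq_len(n),
                         path = sprintf("phantom_%05d.png", seq_len(n)),
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) write_gray_png(imgs[, , i], file.path(out_dir, manifest$path[i]))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(images = imgs, manifest = manifest, spec = spec)
}

lesion_blob <- function(S, center, radius, irregularity, contrast, texture_sd,
                        texture_scale, background = 40) {
  yy <- matrix(seq_len(S), S, S) - center[1]
  xx <- matrix(seq_len(S), S, S, byrow = TRUE) - center[2]
  r <- sqrt(yy^2 + xx^2)
  ang <- atan2(xx, yy)
  nlobe <- 5L
  ph <- stats::runif(nlobe, 0, 2 * pi)
  wob <- rep(0, length(ang))
  for (k in seq_len(nlobe)) wob <- wob + sin(k * ang + ph[k]) / k
  edge <- radius * (1 + irregularity * 0.25 * wob)
  img <- matrix(background, S, S) + contrast * stats::plogis((edge - r) * 2)
  if (texture_sd > 0) {
    noise <- matrix(stats::rnorm(S * S, 0, texture_sd), S, S)
    if (texture_scale > 1) {
      # low-frequency texture: average over a moving window
      k <- as.integer(texture_scale)
      noise <- box_blur(noise, k) * texture_scale
    }
    img <- img + noise
  }
  pmin(pmax(img, 0), 255)
}

box_blur <- function(m, k) {
  cs <- apply(m, 2, function(col) stats::filter(col, rep(1 / k, k), sides = 2))
  cs[is.na(cs)] <- m[is.na(cs)]
  rs <- t(apply(cs, 1, function(row) stats::filter(row, rep(1 / k, k), sides = 2)))
  rs[is.na(rs)] <- cs[is.na(rs)]
  rs
}

#' Generate an imbalanced two-class lesion-patch set
#'
#' Emulates a malignant/benign lesion-patch cohort: both classes are bright
#' blobs on a darker background; malignant lesions are more irregular,
#' higher-contrast and carry fine-grained speckle texture, benign lesions
#' are rounder, dimmer and smoother. `separability` interpolates the
#' malignant parameters between the benign ones (0, classes identically
#' distributed) and full contrast (1, default).
#'
#' @param n_malignant,n_benign Class counts, defaults 75 and 250.
#' @param size Patch side length, default 35.
#' @param seed RNG seed.
#' @param separability Class-separation knob in `[0, 1]`.
#' @param out_dir Optional directory for PNGs + manifest.
#' @return List with `images` (`size x size x n`), `labels` (factor,
#'   malignant/benign), `centers` (n x 2 matrix, 1-based row/col) and
#'   `manifest`.
#' @export
generate_lesion_dataset <- function(n_malignant = 75L, n_benign = 250L,
                                    size = 35L, seed = 1L, separability = 1,
                                    out_dir = NULL) {
  stopifnot(n_malignant >= 1, n_benign >= 1, separability >= 0, separability <= 1)
  set.seed(seed)
  n <- n_malignant + n_benign
  labels <- factor(rep(c("malignant", "benign"), c(n_malignant, n_benign)),
                   levels = c("malignant", "benign"))
  imgs <- array(0, c(size, size, n))
  centers <- matrix(0L, n, 2L)
  sep <- separability
  for (i in seq_len(n)) {
    center <- round(size / 2 + stats::runif(2, -2, 2))
    radius <- stats::runif(1, size * 0.18, size * 0.26)
    if (labels[i] == "malignant") {
      img <- lesion_blob(size, center, radius * (1 + 0.15 * sep),
                         irregularity = sep, contrast = 110 + 60 * sep,
                         texture_sd = 6 + 10 * sep, texture_scale = 1,
                         background = 40)
    } else {
      img <- lesion_blob(size, center, radius, irregularity = 0,
                         contrast = 110, texture_sd = 6,
                         texture_scale = 1 + 2 * sep, background = 40)
    }
    imgs[, , i] <- img
    centers[i, ] <- center
  }
  manifest <- data.frame(id = seq_len(n),
                         path = sprintf("lesion_%04d.png", seq_len(n)),
                         center_row = centers[, 1] - 1L,
                         center_col = centers[, 2] - 1L,
                         label = as.character(labels),
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) write_gray_png(imgs[, , i], file.path(out_dir, manifest$path[i]))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(images = imgs, labels = labels, centers = centers, manifest = manifest)
}

#' Generate structureless noise images
#'
#' Draws uniform white-noise images, box-smoothing (and re-stretching) every
#' second one so the set spans both fine- and coarse-grained structureless
#' texture. Used as the negative class when training the quality-metric
#' classifier to recognise phantom-like structure.
#'
#' @param n Number of images.
#' @param size Side length.
#' @param seed RNG seed.
#' @return Array `(size, size, n)` in `[0, 255]`.
#' @export
generate_noise_images <- function(n, size, seed = 1L) {
  stopifnot(n >= 1, size >= 3)
  set.seed(seed)
  out <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    m <- matrix(stats::runif(size * size, 0, 255), size, size)
    if (i %% 2 == 0) {
      sm <- box_blur(m, 3L)
      m <- (sm - min(sm)) / max(1e-9, diff(range(sm))) * 255
    }
    out[, , i] <- m
  }
  out
}

#' Slice a 3-D volume into axial 2-D images
#'
#' @param volume 3-D array `(H, W, depth)`.
#' @return List of `depth` matrices, slice order preserved.
#' @export
slice_volume <- function(volume) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stop("slice_volume(): input must be a 3-D array")
  if (d[3] == 0L) stop("slice_volume(): empty volume")
  lapply(seq_len(d[3]), function(k) volume[, , k])
}

reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j + 1L))
}

#' Crop a fixed region of interest around a lesion center
#'
#' Extracts a `side x side` patch centred on the lesion; for `side = 35` the
#' center lands on patch pixel `(18, 18)` (1-based). Regions outside the
#' image are reflect-padded.
#'
#' @param img Image matrix.
#' @param center Length-2 integer `(row, col)`, 1-based, inside the image.
#'   (Manifest CSVs store 0-based coordinates; add 1 when reading.)
#' @param side Patch side, default 35.
#' @return `side x side` matrix.
#' @export
roi_crop <- function(img, center, side = 35L) {
  stopifnot(is.matrix(img), length(center) == 2L)
  H <- nrow(img); W <- ncol(img)
  if (side > H || side > W) stop("roi_crop(): side exceeds image dimension")
  if (center[1] < 1 || center[1] > H || center[2] < 1 || center[2] > W)
    stop("roi_crop(): center outside image bounds")
  half <- (side - 1L) %/% 2L
  rows <- reflect_index(seq(center[1] - half, center[1] + (side - 1L - half)), H)
  cols <- reflect_index(seq(center[2] - half, center[2] + (side - 1L - half)), W)
  img[rows, cols, drop = FALSE]
}

#' Augmentation configuration
#'
#' @param rotation Max absolute rotation (degrees), default 15.
#' @param translation Max absolute translation (pixels), default 3.
#' @param scale Scale range, default `c(0.9, 1.1)`.
#' @param crop_jitter Extra crop-window jitter (pixels), default 1.
#' @param noise_sd Additive Gaussian noise sd (gray levels), default 5.
#' @param seed RNG seed used by [expand_with_originals()].
#' @return List of class `capgan_aug_config`.
#' @export
augmentation_config <- function(rotation = 15, translation = 3,
                                scale = c(0.9, 1.1), crop_jitter = 1,
                                noise_sd = 5, seed = 1L) {
  stopifnot(rotation >= 0, translation >= 0, length(scale) == 2L,
            all(scale > 0), diff(scale) >= 0, crop_jitter >= 0, noise_sd >= 0)
  structure(list(rotation = rotation, translation = translation,
                 scale = scale, crop_jitter = crop_jitter,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "capgan_aug_config")
}

affine_warp <- function(img, theta = 0, scale = 1, shift = c(0, 0)) {
  H <- nrow(img); W <- ncol(img)
  if (theta == 0 && scale == 1 && all(shift == 0)) return(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse map: rotate by -theta, scale by 1/scale, un-shift
  ct <- cos(-theta); st <- sin(-theta)
  sy <- (ct * (yy - shift[1]) - st * (xx - shift[2])) / scale + cy
  sx <- (st * (yy - shift[1]) + ct * (xx - shift[2])) / scale + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  cl <- function(v, n) pmin(pmax(as.vector(v), 1), n)
  at <- function(r, c) matrix(img[cbind(r, c)], H, W)
  out <- (1 - fy) * (1 - fx) * at(cl(y0, H), cl(x0, W)) +
    (1 - fy) * fx * at(cl(y0, H), cl(x0 + 1, W)) +
    fy * (1 - fx) * at(cl(y0 + 1, H), cl(x0, W)) +
    fy * fx * at(cl(y0 + 1, H), cl(x0 + 1, W))
  out
}

#' Randomly augment one image
#'
#' Draws `k` independent random rotation/translation/scale transforms
#' (single bilinear warp each, edge-clamped), then adds Gaussian noise.
#' Output size equals input size. With an all-zero-magnitude configuration
#' the outputs are exact copies. Uses the current RNG state; seed via
#' `set.seed()` or use [expand_with_originals()] for a self-seeded batch run.
#'
#' @param img Image matrix in `[0, 255]`.
#' @param config From [augmentation_config()].
#' @param k Number of augmented copies, `>= 1`.
#' @return Array `nrow x ncol x k`.
#' @export
augment <- function(img, config = augmentation_config(), k = 1L) {
  stopifnot(k >= 1)
  H <- nrow(img); W <- ncol(img)
  out <- array(0, c(H, W, k))
  tr <- config$translation + config$crop_jitter
  for (j in seq_len(k)) {
    theta <- stats::runif(1, -config$rotation, config$rotation) * pi / 180
    sc <- stats::runif(1, config$scale[1], config$scale[2])
    shift <- stats::runif(2, -tr, tr)
    a <- affine_warp(img, theta, sc, shift)
    if (config$noise_sd > 0)
      a <- a + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
    out[, , j] <- pmin(pmax(a, 0), 255)
  }
  out
}

#' Expand a dataset with augmented copies
#'
#' Returns the originals followed by `k` augmented copies of each image, so
#' `n` inputs become `n * (k + 1)` outputs. Deterministic per
#' `config$seed`.
#'
#' @param images Array `(H, W, n)`.
#' @param config From [augmentation_config()].
#' @param k Augmented copies per image, default 20; `k = 0` returns the
#'   originals.
#' @return Array `(H, W, n * (k + 1))`, originals first.
#' @export
expand_with_originals <- function(images, config = augmentation_config(),
                                  k = 20L) {
  stopifnot(k >= 0)
  d <- dim(images)
  n <- d[3]
  if (k == 0L) return(images)
  set.seed(config$seed)
  out <- array(0, c(d[1], d[2], n * (k + 1L)))
  out[, , seq_len(n)] <- images
  for (i in seq_len(n)) {
    out[, , n + (i - 1L) * k + seq_len(k)] <- augment(images[, , i], config, k)
  }
  out
}

#' Stratified train/test split
#'
#' Random per-class proportional split with round-to-nearest class counts;
#' the two index sets are disjoint and exhaustive.
#'
#' @param labels Factor/character class labels.
#' @param train_fraction Fraction in `(0, 1)`, default 0.8.
#' @param seed RNG seed.
#' @param stratified Stratify by class (default TRUE).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.8, seed = 1L,
                          stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- as.factor(labels)
  set.seed(seed)
  n <- length(labels)
  if (!stratified) {
    k <- round(n * train_fraction)
    tr <- sort(sample.int(n, k))
    return(list(train = tr, test = setdiff(seq_len(n), tr)))
  }
  tr <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < 2L)
      stop(sprintf("split_dataset(): class '%s' has fewer than 2 members", lv))
    k <- round(length(idx) * train_fraction)
    k <- min(max(k, 1L), length(idx) - 1L)
    tr <- c(tr, sample(idx, k))
  }
  tr <- sort(tr)
  list(train = tr, test = setdiff(seq_len(n), tr))
}

write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(floor(img + 0.5), 0), 255) / 255, path)
}

read_gray_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m * 255
}

write_manifest <- function(df, path) {
  con <- file(path, "w")
  writeLines("# capgan manifest; coordinates 0-based (row, col)", con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

read_manifest <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
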