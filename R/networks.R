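# Generator and discriminator assemblies.
#
# Both networks are plain parameter lists plus precomputed convolution
# geometries; forward passes return caches that the matching backward pass
# consumes. The generator follows the DCGAN template: a dense projection of
# the latent vector to a 4x4 seed map, then stride-2 transposed convolutions
# doubling the resolution per stage, batch norm + ReLU on hidden layers and
# Tanh on the output. The capsule discriminator is a 9x9 convolution front
# end (BN + LeakyReLU), a primary-capsule convolution reshaped into 8-D
# vectors and squashed, and routing into a single 16-D output capsule whose
# L2 norm is the realness score.

#' Generator configuration
#'
#' @param image_size Output side length; power of two between 16 and 64.
#' @param latent_dim Latent dimension, default 100.
#' @param base_channels Channels of the last hidden stage; the 4x4 seed map
#'   has `base_channels * 2^(n_stages-1)` channels. Default 128 at 64x64
#'   (giving the 1024-channel seed), 64 at smaller sizes.
#' @param prior Latent prior, `"gaussian"` (default) or `"uniform"` on
#'   `[-1, 1]`.
#' @param seed Seed for parameter initialisation.
#' @return List of class `capgan_g_config`.
#' @export
generator_config <- function(image_size = 64L, latent_dim = 100L,
                             base_channels = NULL,
                             prior = c("gaussian", "uniform"), seed = 1L) {
  prior <- match.arg(prior)
  if (!image_size %in% c(16L, 32L, 64L))
    stop("generator_config(): image_size must be one of 16, 32, 64")
  n_stages <- as.integer(log2(image_size / 4))
  if (is.null(base_channels))
    base_channels <- switch(as.character(image_size), "64" = 128L, "32" = 64L, 32L)
  # channels after each deconv stage; last stage emits the grayscale image.
  # The 4x4 seed map has base_channels * 2^(n_stages-1) channels (1024 for
  # the 64x64 / base 128 configuration), halving per stage.
  ch <- if (n_stages >= 2L) c(base_channels * 2^seq(n_stages - 2L, 0L), 1L) else 1L
  structure(list(image_size = as.integer(image_size),
                 latent_dim = as.integer(latent_dim),
                 base_channels = as.integer(base_channels),
                 n_stages = n_stages,
                 seed_channels = as.integer(base_channels * 2^(n_stages - 1L)),
                 stage_channels = as.integer(ch), prior = prior,
                 seed = as.integer(seed)),
            class = "capgan_g_config")
}

#' Capsule / convolutional discriminator configuration
#'
#' @param image_size Input side length (16, 32 or 64).
#' @param type `"capsule"` (default) or `"conv"` for the plain DCGAN-style
#'   baseline.
#' @param conv1_filters Filters of the 9x9 front-end convolution.
#' @param primary_kernel Kernel of the primary-capsule convolution; defaults
#'   to 9 where it fits the post-front-end map, otherwise 5.
#' @param n_groups Number of 8-D primary-capsule channel groups.
#' @param caps_dim Primary capsule dimension, default 8.
#' @param out_caps_dim Output capsule dimension, default 16.
#' @param routing_iters Routing iterations, default 3.
#' @param activation Routing activation: `"leaky_relu"` (default, as used in
#'   this model) or `"squash"` for the classic capsule network.
#' @param primary_squash Apply squash to primary capsules (default TRUE).
#' @param slope LeakyReLU negative slope, default 0.2.
#' @param head For `type = "conv"`: `"linear"` (least-squares) or
#'   `"sigmoid"`.
#' @param seed Seed for parameter initialisation.
#' @return List of class `capgan_d_config`.
#' @export
discriminator_config <- function(image_size = 64L,
                                 type = c("capsule", "conv"),
                                 conv1_filters = NULL, primary_kernel = NULL,
                                 n_groups = 8L, caps_dim = 8L,
                                 out_caps_dim = 16L, routing_iters = 3L,
                                 activation = c("leaky_relu", "squash"),
                                 primary_squash = TRUE, slope = 0.2,
                                 head = c("linear", "sigmoid"), seed = 2L) {
  type <- match.arg(type)
  activation <- match.arg(activation)
  head <- match.arg(head)
  if (!image_size %in% c(16L, 32L, 64L))
    stop("discriminator_config(): image_size must be one of 16, 32, 64")
  if (is.null(conv1_filters)) conv1_filters <- if (image_size >= 32L) 64L else 32L
  h1 <- image_size - 8L                       # after 9x9 valid conv
  if (is.null(primary_kernel)) primary_kernel <- if (h1 >= 9L) 9L else 5L
  if (primary_kernel > h1)
    stop("discriminator_config(): primary kernel does not fit feature map")
  structure(list(image_size = as.integer(image_size), type = type,
                 conv1_filters = as.integer(conv1_filters),
                 conv1_kernel = 9L, primary_kernel = as.integer(primary_kernel),
                 primary_stride = 2L, n_groups = as.integer(n_groups),
                 caps_dim = as.integer(caps_dim),
                 out_caps_dim = as.integer(out_caps_dim),
                 routing_iters = as.integer(routing_iters),
                 activation = activation, primary_squash = primary_squash,
                 slope = slope, head = head, seed = as.integer(seed)),
            class = "capgan_d_config")
}

init_w <- function(dims, sd = 0.02) array(stats::rnorm(prod(dims), 0, sd), dims)

#' Initialise generator parameters and buffers
#'
#' @param config From [generator_config()].
#' @return List with `params` (trainable arrays), `buffers` (batch-norm
#'   running statistics), `geoms` (precomputed deconv geometries) and
#'   `config`.
#' @export
init_generator <- function(config) {
  set.seed(config$seed)
  ns <- config$n_stages
  C0 <- config$seed_channels
  ch_in <- c(C0, config$stage_channels[-ns])
  ch_out <- config$stage_channels
  params <- list(
    fc_W = init_w(c(16L * C0, config$latent_dim)),
    fc_b = numeric(16L * C0),
    bn0_gamma = rep(1, C0), bn0_beta = numeric(C0)
  )
  buffers <- list(bn0_mean = numeric(C0), bn0_var = rep(1, C0))
  geoms <- vector("list", ns)
  size <- 4L
  for (k in seq_len(ns)) {
    big <- size * 2L
    geoms[[k]] <- conv_geom(big, big, ch_out[k], 4L, 4L, stride = 2L, pad = 1L)
    params[[paste0("dec", k, "_W")]] <- init_w(c(16L * ch_out[k], ch_in[k]))
    params[[paste0("dec", k, "_b")]] <- numeric(ch_out[k])
    if (k < ns) {
      params[[paste0("bn", k, "_gamma")]] <- rep(1, ch_out[k])
      params[[paste0("bn", k, "_beta")]] <- numeric(ch_out[k])
      buffers[[paste0("bn", k, "_mean")]] <- numeric(ch_out[k])
      buffers[[paste0("bn", k, "_var")]] <- rep(1, ch_out[k])
    }
    size <- big
  }
  list(params = params, buffers = buffers, geoms = geoms, config = config)
}

#' Sample a latent batch
#'
#' @param n Batch size.
#' @param config Generator configuration (gives dimension and prior).
#' @return Matrix `(latent_dim, n)`.
#' @export
sample_latent <- function(n, config) {
  d <- config$latent_dim
  if (config$prior == "gaussian") matrix(stats::rnorm(d * n), d, n)
  else matrix(stats::runif(d * n, -1, 1), d, n)
}

#' Generator forward pass
#'
#' @param model From [init_generator()].
#' @param z Latent matrix `(latent_dim, batch)`.
#' @param train Batch-norm mode: `TRUE` uses batch statistics and updates the
#'   running buffers, `FALSE` uses the stored running statistics.
#' @return List with `x` (images, matrix `(H*W, batch)`, values in `[-1,1]`),
#'   `cache` for the backward pass, and `buffers` (updated running stats).
#' @export
generator_forward <- function(model, z, train = TRUE) {
  cfg <- model$config; p <- model$params; buf <- model$buffers
  if (nrow(z) != cfg$latent_dim) stop("generator_forward(): z has wrong latent dimension")
  cache <- list()
  fc <- dense_forward(z, p$fc_W, p$fc_b); cache$fc <- fc$cache
  bn <- bn_forward(fc$y, p$bn0_gamma, p$bn0_beta, P = 16L,
                   buf$bn0_mean, buf$bn0_var, train = train)
  buf$bn0_mean <- bn$run_mean; buf$bn0_var <- bn$run_var
  cache$bn0 <- bn$cache
  a <- relu_forward(bn$y); cache$relu0 <- a$cache
  h <- a$y
  ns <- cfg$n_stages
  for (k in seq_len(ns)) {
    dc <- deconv_forward(h, p[[paste0("dec", k, "_W")]],
                         p[[paste0("dec", k, "_b")]], model$geoms[[k]])
    cache[[paste0("dec", k)]] <- dc$cache
    if (k < ns) {
      Pk <- model$geoms[[k]]$in_h * model$geoms[[k]]$in_w
      bn <- bn_forward(dc$y, p[[paste0("bn", k, "_gamma")]],
                       p[[paste0("bn", k, "_beta")]], P = Pk,
                       buf[[paste0("bn", k, "_mean")]],
                       buf[[paste0("bn", k, "_var")]], train = train)
      buf[[paste0("bn", k, "_mean")]] <- bn$run_mean
      buf[[paste0("bn", k, "_var")]] <- bn$run_var
      cache[[paste0("bn", k)]] <- bn$cache
      a <- relu_forward(bn$y); cache[[paste0("relu", k)]] <- a$cache
      h <- a$y
    } else {
      th <- tanh_forward(dc$y); cache$tanh <- th$cache
      h <- th$y
    }
  }
  list(x = h, cache = cache, buffers = buf)
}

#' Generator backward pass
#'
#' @param model From [init_generator()].
#' @param dx Gradient of the loss w.r.t. the generated images.
#' @param cache Cache from [generator_forward()].
#' @return Named list of parameter gradients.
#' @export
generator_backward <- function(model, dx, cache) {
  cfg <- model$config
  grads <- list()
  ns <- cfg$n_stages
  d <- tanh_backward(dx, cache$tanh)
  for (k in rev(seq_len(ns))) {
    if (k < ns) {
      d <- relu_backward(d, cache[[paste0("relu", k)]])
      bb <- bn_backward(d, cache[[paste0("bn", k)]])
      grads[[paste0("bn", k, "_gamma")]] <- bb$dgamma
      grads[[paste0("bn", k, "_beta")]] <- bb$dbeta
      d <- bb$dx
    }
    db <- deconv_backward(d, cache[[paste0("dec", k)]])
    grads[[paste0("dec", k, "_W")]] <- db$dW
    grads[[paste0("dec", k, "_b")]] <- db$db
    d <- db$dx
  }
  d <- relu_backward(d, cache$relu0)
  bb <- bn_backward(d, cache$bn0)
  grads$bn0_gamma <- bb$dgamma; grads$bn0_beta <- bb$dbeta
  d <- bb$dx
  dd <- dense_backward(d, cache$fc)
  grads$fc_W <- dd$dW; grads$fc_b <- dd$db
  grads
}

#' Initialise discriminator parameters and buffers
#'
#' Routing transform weights are drawn from a zero-mean normal with sd 0.01;
#' convolution weights use sd 0.02.
#'
#' @param config From [discriminator_config()].
#' @return List with `params`, `buffers`, `geoms`, derived sizes and `config`.
#' @export
init_discriminator <- function(config) {
  set.seed(config$seed)
  S <- config$image_size
  if (config$type == "conv") {
    g1 <- conv_geom(S, S, 1L, 4L, 4L, stride = 2L, pad = 1L)
    F1 <- config$conv1_filters
    g2 <- conv_geom(g1$out_h, g1$out_w, F1, 4L, 4L, stride = 2L, pad = 1L)
    F2 <- 2L * F1
    flat <- g2$out_h * g2$out_w * F2
    params <- list(c1_W = init_w(c(g1$K, F1)), c1_b = numeric(F1),
                   c2_W = init_w(c(g2$K, F2)), c2_b = numeric(F2),
                   bn2_gamma = rep(1, F2), bn2_beta = numeric(F2),
                   fc_W = init_w(c(1L, flat)), fc_b = numeric(1L))
    buffers <- list(bn2_mean = numeric(F2), bn2_var = rep(1, F2))
    return(list(params = params, buffers = buffers,
                geoms = list(g1 = g1, g2 = g2), flat = flat, config = config))
  }
  F1 <- config$conv1_filters
  g1 <- conv_geom(S, S, 1L, config$conv1_kernel, config$conv1_kernel,
                  stride = 1L, pad = 0L)
  Fc <- config$n_groups * config$caps_dim
  g2 <- conv_geom(g1$out_h, g1$out_w, F1, config$primary_kernel,
                  config$primary_kernel, stride = config$primary_stride,
                  pad = 0L)
  n_caps <- g2$out_h * g2$out_w * config$n_groups
  params <- list(c1_W = init_w(c(g1$K, F1)), c1_b = numeric(F1),
                 bn1_gamma = rep(1, F1), bn1_beta = numeric(F1),
                 c2_W = init_w(c(g2$K, Fc)), c2_b = numeric(Fc),
                 route_W = init_w(c(config$out_caps_dim,
                                    config$caps_dim * n_caps), sd = 0.01))
  buffers <- list(bn1_mean = numeric(F1), bn1_var = rep(1, F1))
  list(params = params, buffers = buffers, geoms = list(g1 = g1, g2 = g2),
       n_caps = n_caps, config = config)
}

#' Discriminator forward pass
#'
#' Returns one realness score per sample: the L2 norm of the single output
#' capsule for the capsule discriminator, or the (optionally sigmoid) head
#' output for the convolutional baseline. With one output capsule the
#' coupling coefficients of routing-by-agreement are identically 1 (softmax
#' over a single class), so the routed output equals the activated sum of
#' the prediction vectors for any number of iterations.
#'
#' @param model From [init_discriminator()].
#' @param x Image matrix `(H*W, batch)` in model range `[-1, 1]`.
#' @param train Batch-norm mode as in [generator_forward()].
#' @return List with `score` (numeric vector, one per sample), `cache`,
#'   `buffers`.
#' @export
discriminator_forward <- function(model, x, train = TRUE) {
  cfg <- model$config; p <- model$params; buf <- model$buffers
  if (nrow(x) != cfg$image_size^2) stop("discriminator_forward(): image size mismatch")
  B <- ncol(x)
  cache <- list(B = B)
  if (cfg$type == "conv") {
    c1 <- conv_forward(x, p$c1_W, p$c1_b, model$geoms$g1); cache$c1 <- c1$cache
    a1 <- lrelu_forward(c1$y, cfg$slope); cache$a1 <- a1$cache
    c2 <- conv_forward(a1$y, p$c2_W, p$c2_b, model$geoms$g2); cache$c2 <- c2$cache
    P2 <- model$geoms$g2$out_h * model$geoms$g2$out_w
    bn <- bn_forward(c2$y, p$bn2_gamma, p$bn2_beta, P = P2,
                     buf$bn2_mean, buf$bn2_var, train = train)
    buf$bn2_mean <- bn$run_mean; buf$bn2_var <- bn$run_var; cache$bn2 <- bn$cache
    a2 <- lrelu_forward(bn$y, cfg$slope); cache$a2 <- a2$cache
    fc <- dense_forward(a2$y, p$fc_W, p$fc_b); cache$fc <- fc$cache
    logit <- as.numeric(fc$y)
    score <- if (cfg$head == "sigmoid") stats::plogis(logit) else logit
    cache$logit <- logit
    return(list(score = score, cache = cache, buffers = buf))
  }
  c1 <- conv_forward(x, p$c1_W, p$c1_b, model$geoms$g1); cache$c1 <- c1$cache
  P1 <- model$geoms$g1$out_h * model$geoms$g1$out_w
  bn <- bn_forward(c1$y, p$bn1_gamma, p$bn1_beta, P = P1,
                   buf$bn1_mean, buf$bn1_var, train = train)
  buf$bn1_mean <- bn$run_mean; buf$bn1_var <- bn$run_var; cache$bn1 <- bn$cache
  a1 <- lrelu_forward(bn$y, cfg$slope); cache$a1 <- a1$cache
  c2 <- conv_forward(a1$y, p$c2_W, p$c2_b, model$geoms$g2); cache$c2 <- c2$cache
  # channel-fastest layout: capsule dim varies fastest, so the reshape into
  # capsule columns (caps_dim, N*B) is a zero-copy reinterpretation
  dm <- cfg$caps_dim; N <- model$n_caps
  u <- c2$y
  dim(u) <- c(dm, N * B)
  if (cfg$primary_squash) {
    sq <- squash_cols_forward(u); cache$sq <- sq$cache
    u <- sq$y
  }
  um <- u; dim(um) <- c(dm * N, B)
  cache$um <- um
  s <- p$route_W %*% um                        # (out_dim, B): single capsule
  if (cfg$activation == "squash") {
    va <- squash_cols_forward(s); cache$act <- va$cache
    v <- va$y
  } else {
    va <- lrelu_forward(s, cfg$slope); cache$act <- va$cache
    v <- va$y
  }
  len <- sqrt(colSums(v^2))
  cache$v <- v; cache$len <- len
  list(score = len, cache = cache, buffers = buf)
}

#' Discriminator backward pass
#'
#' @param model From [init_discriminator()].
#' @param dscore Gradient of the loss w.r.t. each sample's score.
#' @param cache Cache from [discriminator_forward()].
#' @return List with `grads` (parameter gradients) and `dx` (gradient w.r.t.
#'   the input images, needed for generator updates).
#' @export
discriminator_backward <- function(model, dscore, cache) {
  cfg <- model$config; p <- model$params
  B <- cache$B
  grads <- list()
  if (cfg$type == "conv") {
    dlogit <- dscore
    if (cfg$head == "sigmoid") {
      sg <- stats::plogis(cache$logit)
      dlogit <- dscore * sg * (1 - sg)
    }
    dd <- dense_backward(matrix(dlogit, 1L, B), cache$fc)
    grads$fc_W <- dd$dW; grads$fc_b <- dd$db
    d <- lrelu_backward(dd$dx, cache$a2)
    bb <- bn_backward(d, cache$bn2)
    grads$bn2_gamma <- bb$dgamma; grads$bn2_beta <- bb$dbeta
    cb <- conv_backward(bb$dx, cache$c2)
    grads$c2_W <- cb$dW; grads$c2_b <- cb$db
    d <- lrelu_backward(cb$dx, cache$a1)
    cb <- conv_backward(d, cache$c1)
    grads$c1_W <- cb$dW; grads$c1_b <- cb$db
    return(list(grads = grads, dx = cb$dx))
  }
  len <- pmax(cache$len, 1e-12)
  dv <- sweep(cache$v, 2L, dscore / len, `*`)
  ds <- if (cfg$activation == "squash") squash_cols_backward(dv, cache$act)
        else lrelu_backward(dv, cache$act)
  grads$route_W <- tcrossprod(ds, cache$um)
  dum <- crossprod(p$route_W, ds)              # (dim*N, B)
  dm <- cfg$caps_dim; N <- model$n_caps
  du <- dum; dim(du) <- c(dm, N * B)
  if (cfg$primary_squash) du <- squash_cols_backward(du, cache$sq)
  dim(du) <- c(dm * N, B)
  cb <- conv_backward(du, cache$c2)
  grads$c2_W <- cb$dW; grads$c2_b <- cb$db
  d <- lrelu_backward(cb$dx, cache$a1)
  bb <- bn_backward(d, cache$bn1)
  grads$bn1_gamma <- bb$dgamma; grads$bn1_beta <- bb$dbeta
  cb <- conv_backward(bb$dx, cache$c1)
  grads$c1_W <- cb$dW; grads$c1_b <- cb$db
  list(grads = grads, dx = cb$dx)
}

#' Convert model-range images to 8-bit pixel range
#'
#' Maps `[-1, 1]` to `[0, 255]` via `y = (x + 1) * 127.5`.
#'
#' @param x Numeric array/matrix with values in `[-1, 1]`.
#' @return Same shape, values in `[0, 255]`.
#' @export
to_pixels <- function(x) {
  if (any(x < -1 - 1e-9) || any(x > 1 + 1e-9))
    stop("to_pixels(): input outside model range [-1, 1]")
  (pmin(pmax(x, -1), 1) + 1) * 127.5
}

#' Convert 8-bit pixel-range images to model range
#'
#' Inverse of [to_pixels()]: `x = y / 127.5 - 1`.
#'
#' @param y Numeric array/matrix with values in `[0, 255]`.
#' @return Same shape, values in `[-1, 1]`.
#' @export
from_pixels <- function(y) {
  if (any(y < -1e-9) || any(y > 255 + 1e-9))
    stop("from_pixels(): input outside pixel range [0, 255]")
  pmin(pmax(y, 0), 255) / 127.5 - 1
}
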