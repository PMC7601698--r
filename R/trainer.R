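# Adversarial training: alternating least-squares (or cross-entropy)
# updates of the discriminator and generator with Adam, seeded substreams,
# checkpointing and sample generation.

# One master seed fans out into named substreams so that, e.g., parameter
# initialisation and latent sampling stay decoupled.
derive_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Training configuration
#'
#' @param steps Number of generator update steps.
#' @param batch_size Mini-batch size, default 64.
#' @param learning_rate Adam learning rate, default 2e-4.
#' @param beta1 Adam first-moment decay, default 0.5.
#' @param d_steps_per_g_step Discriminator updates per generator update.
#' @param loss_mode `"least_squares"` (default) or `"cross_entropy"`.
#' @param seed Master seed.
#' @param checkpoint_every Steps between checkpoints when a run directory is
#'   given; 0 disables intermediate checkpoints.
#' @return List of class `capgan_train_config`.
#' @export
train_config <- function(steps = 2000L, batch_size = 64L,
                         learning_rate = 2e-4, beta1 = 0.5,
                         d_steps_per_g_step = 1L,
                         loss_mode = c("least_squares", "cross_entropy"),
                         seed = 1L, checkpoint_every = 0L) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(steps >= 1, batch_size >= 1, learning_rate > 0,
            beta1 > 0, beta1 < 1, d_steps_per_g_step >= 1)
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 loss_mode = loss_mode, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "capgan_train_config")
}

ce_grad_real <- function(s) -(1 - stats::plogis(s))
ce_grad_fake_d <- function(s) stats::plogis(s)

#' Train a capsule-network GAN
#'
#' Alternates discriminator updates (least-squares loss: real target 1,
#' fake target 0) and generator updates (fake target 1) with Adam. With
#' `loss_mode = "cross_entropy"` the discriminator score is treated as a
#' logit and the original minimax objective is used. Fully reproducible
#' given the configuration seeds; aborts with a diagnostic snapshot on
#' non-finite losses.
#'
#' @param images Array `(H, W, n)` in file range `[0, 255]`, or a matrix
#'   `(H*W, n)` already in model range.
#' @param g_config From [generator_config()].
#' @param d_config From [discriminator_config()].
#' @param t_config From [train_config()].
#' @param run_dir Optional directory for checkpoints and a metrics log.
#' @param state Optional state from a previous [train_capgan()] call or
#'   [load_checkpoint()]; training resumes from it.
#' @param verbose Print progress every 500 steps.
#' @return Training state: models, optimiser states, loss traces
#'   (`trace$v_d`, `trace$v_g`), step counter and RNG state.
#' @export
train_capgan <- function(images, g_config = generator_config(16L),
                         d_config = discriminator_config(16L),
                         t_config = train_config(), run_dir = NULL,
                         state = NULL, verbose = FALSE) {
  x_all <- as_model_matrix(images, g_config$image_size)
  n <- ncol(x_all)
  if (n < 1L) stop("train_capgan(): empty dataset")
  B <- t_config$batch_size
  if (is.null(state)) {
    g_model <- init_generator(modifyList(g_config, list(
      seed = derive_seed(t_config$seed, "g_init"))))
    d_model <- init_discriminator(modifyList(d_config, list(
      seed = derive_seed(t_config$seed, "d_init"))))
    class(g_model$config) <- class(g_config)
    class(d_model$config) <- class(d_config)
    state <- list(g = g_model, d = d_model,
                  opt_g = adam_init(g_model$params),
                  opt_d = adam_init(d_model$params),
                  step = 0L,
                  trace = list(v_d = numeric(0), v_g = numeric(0)),
                  t_config = t_config)
    set.seed(derive_seed(t_config$seed, "train_stream"))
  } else {
    if (!is.null(state$rng_state))
      assign(".Random.seed", state$rng_state, envir = globalenv())
  }
  lr <- t_config$learning_rate; b1 <- t_config$beta1
  ls <- t_config$loss_mode == "least_squares"
  for (step in seq_len(t_config$steps)) {
    for (dstep in seq_len(t_config$d_steps_per_g_step)) {
      idx <- sample.int(n, min(B, n))
      xr <- x_all[, idx, drop = FALSE]
      z <- sample_latent(length(idx), state$g$config)
      gf <- generator_forward(state$g, z, train = TRUE)
      state$g$buffers <- gf$buffers
      fr <- discriminator_forward(state$d, xr, train = TRUE)
      state$d$buffers <- fr$buffers
      ff <- discriminator_forward(state$d, gf$x, train = TRUE)
      state$d$buffers <- ff$buffers
      m <- length(idx)
      if (ls) {
        loss_d <- ls_discriminator_loss(fr$score, ff$score)
        dsr <- (fr$score - 1) / m
        dsf <- ff$score / m
      } else {
        loss_d <- -mean(log(pmax(stats::plogis(fr$score), 1e-7))) -
          mean(log(pmax(1 - stats::plogis(ff$score), 1e-7)))
        dsr <- ce_grad_real(fr$score) / m
        dsf <- ce_grad_fake_d(ff$score) / m
      }
      if (!is.finite(loss_d)) abort_nan(state, run_dir, "discriminator")
      br <- discriminator_backward(state$d, dsr, fr$cache)
      bf <- discriminator_backward(state$d, dsf, ff$cache)
      grads <- mapply(`+`, br$grads[names(state$d$params)],
                      bf$grads[names(state$d$params)], SIMPLIFY = FALSE)
      upd <- adam_step(state$d$params, grads, state$opt_d, lr = lr, beta1 = b1)
      state$d$params <- upd$params; state$opt_d <- upd$state
    }
    z <- sample_latent(B, state$g$config)
    gf <- generator_forward(state$g, z, train = TRUE)
    state$g$buffers <- gf$buffers
    ff <- discriminator_forward(state$d, gf$x, train = TRUE)
    state$d$buffers <- ff$buffers
    if (ls) {
      loss_g <- ls_generator_loss(ff$score)
      dsf <- (ff$score - 1) / B
    } else {
      loss_g <- mean(log(pmax(1 - stats::plogis(ff$score), 1e-7)))
      dsf <- -stats::plogis(ff$score) / B
    }
    if (!is.finite(loss_g)) abort_nan(state, run_dir, "generator")
    db <- discriminator_backward(state$d, dsf, ff$cache)
    g_grads <- generator_backward(state$g, db$dx, gf$cache)
    upd <- adam_step(state$g$params, g_grads[names(state$g$params)],
                     state$opt_g, lr = lr, beta1 = b1)
    state$g$params <- upd$params; state$opt_g <- upd$state
    state$step <- state$step + 1L
    state$trace$v_d <- c(state$trace$v_d, loss_d)
    state$trace$v_g <- c(state$trace$v_g, loss_g)
    if (verbose && state$step %% 500L == 0L)
      message(sprintf("step %d: V_D = %.4f, V_G = %.4f", state$step, loss_d, loss_g))
    if (!is.null(run_dir) && t_config$checkpoint_every > 0L &&
        state$step %% t_config$checkpoint_every == 0L) {
      state$rng_state <- get(".Random.seed", envir = globalenv())
      save_checkpoint(state, file.path(run_dir,
                                       sprintf("checkpoint_%06d.rds", state$step)))
    }
  }
  state$rng_state <- get(".Random.seed", envir = globalenv())
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(state, file.path(run_dir, "checkpoint_final.rds"))
    jsonlite::write_json(
      data.frame(step = seq_along(state$trace$v_d),
                 V_D = state$trace$v_d, V_G = state$trace$v_g),
      file.path(run_dir, "metrics.json"), digits = NA)
  }
  state
}

abort_nan <- function(state, run_dir, which) {
  snap <- file.path(if (is.null(run_dir)) tempdir() else run_dir,
                    "nan_diagnostic.rds")
  saveRDS(state, snap)
  stop(sprintf("train_capgan(): non-finite %s loss at step %d; snapshot at %s",
               which, state$step + 1L, snap))
}

as_model_matrix <- function(images, image_size) {
  if (is.matrix(images)) {
    if (nrow(images) != image_size^2)
      stop("train_capgan(): image matrix does not match configured size")
    if (max(images) > 1 + 1e-9) stop("matrix input must be in model range [-1, 1]")
    return(images)
  }
  d <- dim(images)
  if (length(d) != 3L || d[1] != image_size || d[2] != image_size)
    stop("train_capgan(): images must be (size, size, n)")
  m <- images; dim(m) <- c(d[1] * d[2], d[3])
  from_pixels(m)
}

#' Save a training checkpoint
#'
#' Writes the full training state as RDS plus a JSON sidecar recording the
#' configurations, seed, step and package version.
#'
#' @param state From [train_capgan()].
#' @param path Output `.rds` path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(state, path)
  sidecar <- sub("\\.rds$", ".json", path)
  jsonlite::write_json(list(
    step = state$step,
    seed = state$t_config$seed,
    loss_mode = state$t_config$loss_mode,
    g_config = unclass(state$g$config),
    d_config = unclass(state$d$config),
    package_version = as.character(utils::packageVersion("capgan"))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path Path from [save_checkpoint()].
#' @return Training state.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint(): no such file: ", path)
  state <- tryCatch(readRDS(path), error = function(e)
    stop("load_checkpoint(): corrupt checkpoint: ", conditionMessage(e)))
  if (!all(c("g", "d", "step") %in% names(state)))
    stop("load_checkpoint(): corrupt checkpoint: missing components")
  state
}

#' Warm-start parameters from a checkpoint
#'
#' Copies checkpoint parameter values into an architecture-compatible
#' parameter list (exact restore); errors name the first mismatching layer.
#' Optimiser state is not carried over.
#'
#' @param params Parameter list to overwrite (e.g. from [init_generator()]).
#' @param checkpoint_params Parameter list from a loaded checkpoint.
#' @return The restored parameter list.
#' @export
warm_start <- function(params, checkpoint_params) {
  for (nm in names(params)) {
    if (is.null(checkpoint_params[[nm]]))
      stop("warm_start(): checkpoint lacks layer '", nm, "'")
    a <- dim(params[[nm]]); b <- dim(checkpoint_params[[nm]])
    same <- if (is.null(a) && is.null(b))
      length(params[[nm]]) == length(checkpoint_params[[nm]])
    else identical(a, b)
    if (!same) stop("warm_start(): shape mismatch in layer '", nm, "'")
    params[[nm]] <- checkpoint_params[[nm]]
  }
  params
}

#' Generate images from a trained (or fresh) generator
#'
#' Deterministic given the seed; inference-mode batch norm. Images are
#' returned in file range and optionally written as 8-bit grayscale PNGs
#' (127.5 rounds half-up to 128).
#'
#' @param state Training state or checkpoint (needs `$g`).
#' @param n Number of images.
#' @param seed Seed for the latent draw.
#' @param out_dir Optional directory for PNGs.
#' @return Array `(size, size, n)` in `[0, 255]`.
#' @export
generate_samples <- function(state, n, seed = 1L, out_dir = NULL) {
  if (is.null(state$g)) stop("generate_samples(): state has no generator")
  set.seed(derive_seed(seed, "sample_latent"))
  z <- sample_latent(n, state$g$config)
  gf <- generator_forward(state$g, z, train = FALSE)
  y <- to_pixels(gf$x)
  S <- state$g$config$image_size
  imgs <- array(y, c(S, S, n))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_gray_png(imgs[, , i], file.path(out_dir, sprintf("sample_%05d.png", i)))
  }
  imgs
}
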