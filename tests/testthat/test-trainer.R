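make_phantoms16 <- function(n = 64, seed = 99L) {
  generate_phantoms(n, phantom_spec(image_size = 16L, seed = seed))$images
}

test_that("short training runs are finite and reproducible per seed", {
  imgs <- make_phantoms16(32)
  tc <- train_config(steps = 50L, batch_size = 8L, seed = 7L)
  a <- train_capgan(imgs, generator_config(16L), discriminator_config(16L), tc)
  expect_length(a$trace$v_d, 50L)
  expect_true(all(is.finite(a$trace$v_d)))
  expect_true(all(is.finite(a$trace$v_g)))
  b <- train_capgan(imgs, generator_config(16L), discriminator_config(16L), tc)
  expect_identical(a$trace, b$trace)
  # different seed, different trajectory
  c_ <- train_capgan(imgs, generator_config(16L), discriminator_config(16L),
                     train_config(steps = 50L, batch_size = 8L, seed = 8L))
  expect_false(identical(a$trace, c_$trace))
})

test_that("cross-entropy mode trains the conv baseline", {
  imgs <- make_phantoms16(32)
  st <- train_capgan(imgs, generator_config(16L),
                     discriminator_config(16L, type = "conv", head = "sigmoid"),
                     train_config(steps = 25L, batch_size = 8L, seed = 3L,
                                  loss_mode = "cross_entropy"))
  expect_true(all(is.finite(st$trace$v_d)))
  expect_true(all(st$trace$v_d > 0))      # cross-entropy loss is positive
})

test_that("repeated discriminator updates overfit a frozen fixed batch", {
  set.seed(1)
  d <- init_discriminator(discriminator_config(16L, seed = 3L))
  xr <- matrix(runif(256 * 8, -1, 1), 256, 8)
  xf <- matrix(runif(256 * 8, -1, 1), 256, 8)
  opt <- adam_init(d$params)
  losses <- numeric(200)
  for (k in 1:200) {
    fr <- discriminator_forward(d, xr, train = TRUE); d$buffers <- fr$buffers
    ff <- discriminator_forward(d, xf, train = TRUE); d$buffers <- ff$buffers
    losses[k] <- ls_discriminator_loss(fr$score, ff$score)
    br <- discriminator_backward(d, (fr$score - 1) / 8, fr$cache)
    bf <- discriminator_backward(d, ff$score / 8, ff$cache)
    g <- mapply(`+`, br$grads[names(d$params)], bf$grads[names(d$params)],
                SIMPLIFY = FALSE)
    u <- adam_step(d$params, g, opt, lr = 1e-3)
    d$params <- u$params; opt <- u$state
  }
  expect_lt(losses[200], 1e-4)
  expect_lt(losses[200], losses[1] / 1000)
  # downward trend: successive 25-step block means decrease within tolerance
  blocks <- colMeans(matrix(losses, 25))
  expect_true(all(diff(blocks) < 1e-2))
})

test_that("checkpoints round-trip and resumed training matches one run", {
  imgs <- make_phantoms16(32)
  gc_ <- generator_config(16L); dc_ <- discriminator_config(16L)
  full <- train_capgan(imgs, gc_, dc_,
                       train_config(steps = 30L, batch_size = 8L, seed = 5L))
  part <- train_capgan(imgs, gc_, dc_,
                       train_config(steps = 18L, batch_size = 8L, seed = 5L))
  td <- withr::local_tempdir()
  ck <- file.path(td, "part.rds")
  save_checkpoint(part, ck)
  expect_true(file.exists(sub("rds$", "json", ck)))
  restored <- load_checkpoint(ck)
  resumed <- train_capgan(imgs, gc_, dc_,
                          train_config(steps = 12L, batch_size = 8L, seed = 5L),
                          state = restored)
  expect_equal(resumed$step, 30L)
  expect_equal(resumed$trace$v_d, full$trace$v_d, tolerance = 1e-12)
  expect_equal(resumed$g$params, full$g$params, tolerance = 1e-12)
  expect_error(load_checkpoint(file.path(td, "nope.rds")), "no such file")
})

test_that("warm start restores parameters exactly and checks shapes", {
  g16a <- init_generator(generator_config(16L, seed = 1L))
  g16b <- init_generator(generator_config(16L, seed = 2L))
  restored <- warm_start(g16b$params, g16a$params)
  expect_equal(max(abs(unlist(restored) - unlist(g16a$params))), 0)
  g32 <- init_generator(generator_config(32L, seed = 3L))
  expect_error(warm_start(g32$params, g16a$params), "fc_W")
})

test_that("pretrain-then-finetune pipeline runs end to end", {
  # pretrain on an augmented pool, then warm-start fine-tuning on originals
  orig <- make_phantoms16(12, seed = 4L)
  pool <- expand_with_originals(orig, augmentation_config(seed = 5L), k = 3L)
  gc_ <- generator_config(16L); dc_ <- discriminator_config(16L)
  pre <- train_capgan(pool, gc_, dc_,
                      train_config(steps = 20L, batch_size = 8L, seed = 6L))
  fresh <- train_capgan(orig, gc_, dc_,
                        train_config(steps = 1L, batch_size = 8L, seed = 7L))
  fresh$g$params <- warm_start(fresh$g$params, pre$g$params)
  fresh$d$params <- warm_start(fresh$d$params, pre$d$params)
  fresh$opt_g <- adam_init(fresh$g$params)
  fresh$opt_d <- adam_init(fresh$d$params)
  tuned <- train_capgan(orig, gc_, dc_,
                        train_config(steps = 10L, batch_size = 8L, seed = 7L),
                        state = fresh)
  expect_true(all(is.finite(tuned$trace$v_g)))
})

test_that("sample generation is deterministic, bounded and writes PNGs", {
  imgs <- make_phantoms16(32)
  st <- train_capgan(imgs, generator_config(16L), discriminator_config(16L),
                     train_config(steps = 10L, batch_size = 8L, seed = 9L))
  td <- withr::local_tempdir()
  s1 <- generate_samples(st, 8L, seed = 4L, out_dir = td)
  s2 <- generate_samples(st, 8L, seed = 4L)
  expect_equal(dim(s1), c(16, 16, 8))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 255))
  files <- list.files(td, pattern = "sample_.*\\.png$", full.names = TRUE)
  expect_length(files, 8L)
  # files are 8-bit grayscale and round-trip the pixel values
  back <- png::readPNG(files[1])
  expect_true(is.matrix(back))
  expect_equal(back * 255, pmin(pmax(floor(s1[, , 1] + 0.5), 0), 255),
               tolerance = 1e-9)
  s3 <- generate_samples(st, 8L, seed = 5L)
  expect_false(identical(s1, s3))
})
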