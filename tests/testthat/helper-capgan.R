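# Shared fixtures and oracles, all built in code at test time.

# Independent scalar-loop reference for routing-by-agreement: no vectorised
# shortcuts, mirrors the published algorithm step by step.
reference_routing <- function(u_hat, r, activation = "squash", slope = 0.2) {
  n_in <- dim(u_hat)[1]; n_out <- dim(u_hat)[2]; dim_out <- dim(u_hat)[3]
  act <- function(x) {
    if (activation == "squash") {
      n2 <- sum(x^2)
      if (n2 == 0) return(x * 0)
      (n2 / (1 + n2)) * x / sqrt(n2)
    } else {
      sapply(x, function(e) if (e >= 0) e else slope * e)
    }
  }
  b <- matrix(0, n_in, n_out)
  v <- matrix(0, n_out, dim_out)
  for (it in seq_len(r)) {
    cc <- matrix(0, n_in, n_out)
    for (i in seq_len(n_in)) {
      e <- exp(b[i, ] - max(b[i, ]))
      cc[i, ] <- e / sum(e)
    }
    for (j in seq_len(n_out)) {
      s <- numeric(dim_out)
      for (i in seq_len(n_in)) s <- s + cc[i, j] * u_hat[i, j, ]
      v[j, ] <- act(s)
      for (i in seq_len(n_in)) b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
    }
  }
  v
}

# Central-difference gradient of scalar f at selected indices of x.
numeric_grad <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Evaluation classifier for 16x16 phantom experiments: phantoms vs
# structureless noise.
phantom_eval_model <- function(phantoms, n_each = 500L, seed = 777L) {
  neg <- generate_noise_images(n_each, dim(phantoms)[1], seed)
  tr <- array(c(phantoms[, , seq_len(n_each)], neg),
              c(dim(phantoms)[1], dim(phantoms)[2], 2L * n_each))
  labs <- factor(rep(c("phantom", "other"), each = n_each),
                 levels = c("phantom", "other"))
  train_eval_classifier(tr, labs, feature_params(cell_size = 4L))
}
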