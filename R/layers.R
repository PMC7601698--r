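# Low-level differentiable layers.
#
# Activations are stored as (features x batch) matrices. A spatial tensor of
# height H, width W and C channels is flattened channel-fastest:
# index = c + (h-1)*C + (w-1)*C*H. With this layout the reinterpretations
# between convolution, batch-norm and capsule views are plain dim<-
# assignments (no data movement), which keeps the pure-R training loop fast.
# Every layer is a forward returning list(y, cache) and a backward mapping
# the upstream gradient to list(dx, d<param>...). Convolutions use
# gather/scatter index maps precomputed once per geometry; zero padding is
# realised through a phantom "zero slot" row appended to the input.

conv_geom <- function(in_h, in_w, in_c, kh, kw, stride = 1L, pad = 0L) {
  out_h <- (in_h + 2L * pad - kh) %/% stride + 1L
  out_w <- (in_w + 2L * pad - kw) %/% stride + 1L
  if (out_h < 1L || out_w < 1L)
    stop(sprintf("conv_geom(): kernel %dx%d stride %d does not fit input %dx%d",
                 kh, kw, stride, in_h, in_w))
  in_len <- in_h * in_w * in_c
  zero_slot <- in_len + 1L
  K <- kh * kw * in_c
  P <- out_h * out_w
  # patch element order (c, dh, dw), matching the weight row layout
  ccv <- rep(seq_len(in_c), times = kh * kw)
  dh <- rep(rep(seq_len(kh), each = in_c), times = kw)
  dw <- rep(seq_len(kw), each = in_c * kh)
  oh <- rep(seq_len(out_h), times = out_w)
  ow <- rep(seq_len(out_w), each = out_h)
  ih <- outer(dh, (oh - 1L) * stride - pad, `+`)       # (K, P)
  iw <- outer(dw, (ow - 1L) * stride - pad, `+`)
  inside <- ih >= 1L & ih <= in_h & iw >= 1L & iw <= in_w
  idx <- ccv + (ih - 1L) * in_c + (iw - 1L) * in_c * in_h
  idx[!inside] <- zero_slot
  list(in_h = in_h, in_w = in_w, in_c = in_c, kh = kh, kw = kw,
       stride = stride, pad = pad, out_h = out_h, out_w = out_w,
       in_len = in_len, K = K, P = P, idx = as.vector(idx))
}

conv_forward <- function(x, W, b, geom) {
  B <- ncol(x)
  xa <- rbind(x, 0)
  cols <- xa[geom$idx, , drop = FALSE]          # (K*P, B)
  dim(cols) <- c(geom$K, geom$P * B)
  y <- crossprod(W, cols) + b                   # (F, P*B); b recycles over rows
  FF <- ncol(W)
  dim(y) <- c(FF * geom$P, B)                   # channel-fastest, zero-copy
  list(y = y, cache = list(cols = cols, W = W, geom = geom, B = B, FF = FF))
}

conv_backward <- function(dy, cache) {
  geom <- cache$geom; B <- cache$B; FF <- cache$FF
  dim(dy) <- c(FF, geom$P * B)
  dW <- tcrossprod(cache$cols, dy)              # (K, F)
  db <- rowSums(dy)
  dcols <- cache$W %*% dy                       # (K, P*B)
  dim(dcols) <- c(geom$K * geom$P, B)
  dx <- scatter_rows(dcols, geom$idx, geom$in_len, B)
  list(dx = dx, dW = dW, db = db)
}

scatter_rows <- function(d, idx, in_len, B) {
  r <- rowsum(d, group = idx)
  out <- matrix(0, in_len + 1L, B)
  out[as.integer(rownames(r)), ] <- r
  out[seq_len(in_len), , drop = FALSE]
}

# Transposed convolution over the same geometry object: maps the small grid
# (geom$P positions, Cs channels) to the big grid (geom$in_* sides, in_c
# channels). Weights share the conv layout W (K, Cs); the forward pass is
# the conv's backward-data pass.
deconv_forward <- function(x, W, b, geom) {
  B <- ncol(x)
  Cs <- ncol(W)
  xs <- x
  dim(xs) <- c(Cs, geom$P * B)
  cols <- W %*% xs                              # (K, P*B)
  dim(cols) <- c(geom$K * geom$P, B)
  y <- scatter_rows(cols, geom$idx, geom$in_len, B)
  y <- y + b                                    # channel-fastest: b recycles
  list(y = y, cache = list(xs = xs, W = W, geom = geom, B = B, Cs = Cs))
}

deconv_backward <- function(dy, cache) {
  geom <- cache$geom; B <- cache$B; Cs <- cache$Cs
  Cb <- geom$in_c
  db <- rowSums(matrix(rowSums(dy), Cb))
  dya <- rbind(dy, 0)
  cols <- dya[geom$idx, , drop = FALSE]
  dim(cols) <- c(geom$K, geom$P * B)
  dxs <- crossprod(cache$W, cols)               # (Cs, P*B)
  dW <- tcrossprod(cols, cache$xs)              # (K, Cs)
  dim(dxs) <- c(Cs * geom$P, B)
  list(dx = dxs, dW = dW, db = db)
}

dense_forward <- function(x, W, b) {
  list(y = W %*% x + b, cache = list(x = x, W = W))
}

dense_backward <- function(dy, cache) {
  list(dx = crossprod(cache$W, dy), dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

# Batch normalisation per channel over all positions and samples.
# x is (C*P, B) channel-fastest; gamma/beta length C. Population variance,
# eps 1e-5. Internally works on the (C, P*B) view where per-channel
# statistics are rowMeans and vector recycling does the centring/scaling.
bn_forward <- function(x, gamma, beta, P, run_mean, run_var,
                       train = TRUE, momentum = 0.9, eps = 1e-5) {
  C <- length(gamma); B <- ncol(x)
  X <- x
  dim(X) <- c(C, P * B)
  if (train) {
    mu <- rowMeans(X)
    v <- rowMeans(X^2) - mu^2
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * istd
  y <- xhat * gamma + beta
  dim(y) <- c(C * P, B)
  list(y = y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, P = P, C = C,
                    B = B, train = train))
}

bn_backward <- function(dy, cache) {
  P <- cache$P; C <- cache$C; B <- cache$B
  D <- dy
  dim(D) <- c(C, P * B)
  xhat <- cache$xhat
  dgamma <- rowSums(D * xhat)
  dbeta <- rowSums(D)
  dxhat <- D * cache$gamma
  N <- P * B
  if (cache$train) {
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    dX <- (N * dxhat - s1 - xhat * s2) * (cache$istd / N)
  } else {
    dX <- dxhat * cache$istd
  }
  dim(dX) <- c(C * P, B)
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  m <- x >= 0
  list(y = x * m, cache = m)
}
relu_backward <- function(dy, cache) dy * cache

lrelu_forward <- function(x, slope = 0.2) {
  w <- slope + (1 - slope) * (x >= 0)
  list(y = x * w, cache = w)
}
lrelu_backward <- function(dy, cache) dy * cache

tanh_forward <- function(x) {
  y <- tanh(x)
  list(y = y, cache = y)
}
tanh_backward <- function(dy, cache) dy * (1 - cache^2)

# Squash applied to capsule vectors stored as columns of a (dim, n) matrix.
squash_cols_forward <- function(u) {
  n2 <- colSums(u^2)
  n <- sqrt(n2)
  alpha <- n / (1 + n2)
  v <- u * rep(alpha, each = nrow(u))
  list(y = v, cache = list(u = u, n = n, n2 = n2, alpha = alpha))
}

squash_cols_backward <- function(dv, cache) {
  # v = alpha(n) u with alpha = n/(1+n^2); alpha' = (1-n^2)/(1+n^2)^2
  n <- cache$n; n2 <- cache$n2; u <- cache$u
  dm <- nrow(u)
  dalpha <- (1 - n2) / (1 + n2)^2
  udv <- colSums(u * dv)
  coef <- ifelse(n > 1e-12, dalpha * udv / n, 0)
  dv * rep(cache$alpha, each = dm) + u * rep(coef, each = dm)
}

#' Initialise Adam optimiser state
#'
#' @param params Named list of numeric parameter arrays.
#' @return Optimiser state (first/second moments and step counter).
#' @export
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Adam update
#'
#' @param params,grads Named lists of parameter arrays and their gradients.
#' @param state From [adam_init()].
#' @param lr Learning rate. @param beta1,beta2 Moment decays. @param eps
#'   Numerical floor.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  k1 <- lr / (1 - beta1^state$t)
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    m <- beta1 * state$m[[nm]] + (1 - beta1) * g
    v <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - k1 * m / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}
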