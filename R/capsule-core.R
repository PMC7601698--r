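#' Squash nonlinearity for capsule vectors
#'
#' Scales a capsule vector so that its direction is preserved while its norm
#' is compressed into `[0, 1)`: a vector of norm `n` is mapped to norm
#' `n^2 / (1 + n^2)`. Short vectors shrink towards zero, long vectors
#' approach unit length.
#'
#' @param s Numeric vector (one capsule) or matrix with capsules in columns.
#' @return Object of the same shape as `s`.
#' @examples
#' squash(c(3, 4))        # norm 25/26
#' squash(c(0, 0))        # stays zero
#' @export
squash <- function(s) {
  if (!all(is.finite(s))) stop("squash(): non-finite input")
  if (is.matrix(s)) {
    n2 <- colSums(s^2)
    alpha <- sqrt(n2) / (1 + n2)
    # zero columns: alpha = 0 already
    return(sweep(s, 2, alpha, `*`))
  }
  n2 <- sum(s^2)
  s * (sqrt(n2) / (1 + n2))
}

#' Leaky rectified linear activation
#'
#' Identity for non-negative inputs; negative inputs are passed through with
#' a small slope so that gradient information is retained. Two conventions
#' are supported: the usual multiplicative slope `y = slope * x` (default)
#' and a `literal` mode `y = x / slope`, which amplifies negatives and is
#' provided only for completeness.
#'
#' @param x Numeric vector/array.
#' @param slope Positive scalar slope parameter, default 0.2.
#' @param mode `"multiplicative"` (default) or `"literal"`.
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, slope = 0.2, mode = c("multiplicative", "literal")) {
  mode <- match.arg(mode)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("leaky_relu(): slope must be a positive scalar")
  neg <- if (mode == "multiplicative") x * slope else x / slope
  ifelse(x >= 0, x, neg)
}

#' Softmax over routing logits
#'
#' Converts one row of routing logits (one input capsule's affinities to the
#' output capsules) into coupling coefficients: non-negative and summing to 1.
#'
#' @param b_row Numeric vector of logits.
#' @return Probability vector of the same length.
#' @export
routing_softmax <- function(b_row) {
  if (length(b_row) == 0L) stop("routing_softmax(): empty logit row")
  if (!all(is.finite(b_row))) stop("routing_softmax(): non-finite logits")
  e <- exp(b_row - max(b_row))
  e / sum(e)
}

#' Prediction vectors from lower-layer capsules
#'
#' Applies per-pair linear transforms to lower-layer capsule outputs:
#' `u_hat[i, j] = W[i, j] %*% u[i]`. `W` is a 4-D array indexed
#' `[i, j, dim_out, dim_in]`, `u` a matrix with input capsules in rows.
#'
#' @param u Matrix `(n_in, dim_in)` of lower-layer capsule outputs.
#' @param W Array `(n_in, n_out, dim_out, dim_in)` of transform weights.
#' @return Array `(n_in, n_out, dim_out)` of prediction vectors.
#' @export
predict_vectors <- function(u, W) {
  du <- dim(W)
  if (length(du) != 4L) stop("predict_vectors(): W must be 4-D (n_in, n_out, dim_out, dim_in)")
  if (!is.matrix(u) || nrow(u) != du[1] || ncol(u) != du[4])
    stop("predict_vectors(): shape mismatch between u and W")
  n_in <- du[1]; n_out <- du[2]; dim_out <- du[3]
  u_hat <- array(0, c(n_in, n_out, dim_out))
  for (i in seq_len(n_in)) for (j in seq_len(n_out)) {
    u_hat[i, j, ] <- matrix(W[i, j, , ], dim_out) %*% u[i, ]
  }
  u_hat
}

#' Dynamic routing by agreement
#'
#' Iteratively assigns coupling coefficients between prediction vectors and
#' output capsules. Logits `b` start at zero; each round computes
#' `c = softmax(b)` per input capsule, forms the weighted sums
#' `s_j = sum_i c_ij u_hat_ij`, activates them (`squash` classically, or
#' `leaky_relu` as used in this model's discriminator), and reinforces
#' `b_ij` by the agreement `u_hat_ij . v_j`.
#'
#' @param u_hat Array `(n_in, n_out, dim_out)` of prediction vectors.
#' @param r Number of routing iterations, integer >= 1.
#' @param activation `"squash"` or `"leaky_relu"`.
#' @param slope Slope used when `activation = "leaky_relu"`.
#' @return List with `v` (matrix `(n_out, dim_out)` of output capsules),
#'   `c` (final coupling matrix `(n_in, n_out)`), `b` (final logits).
#' @export
dynamic_routing <- function(u_hat, r = 3L, activation = c("squash", "leaky_relu"),
                            slope = 0.2) {
  activation <- match.arg(activation)
  if (!is.numeric(r) || length(r) != 1L || r < 1) stop("dynamic_routing(): r must be >= 1")
  d <- dim(u_hat)
  if (length(d) != 3L) stop("dynamic_routing(): u_hat must be 3-D (n_in, n_out, dim_out)")
  n_in <- d[1]; n_out <- d[2]; dim_out <- d[3]
  act <- if (activation == "squash") squash else function(x) leaky_relu(x, slope)
  b <- matrix(0, n_in, n_out)
  v <- matrix(0, n_out, dim_out)
  cc <- matrix(1 / n_out, n_in, n_out)
  for (it in seq_len(r)) {
    e <- exp(b - apply(b, 1L, max))
    cc <- e / rowSums(e)
    for (j in seq_len(n_out)) {
      uh_j <- matrix(u_hat[, j, ], n_in, dim_out)
      v[j, ] <- act(colSums(uh_j * cc[, j]))
      b[, j] <- b[, j] + as.numeric(uh_j %*% v[j, ])
    }
  }
  list(v = v, c = cc, b = b)
}

#' Length (existence score) of a capsule vector
#'
#' The Euclidean norm of a capsule's output encodes the probability that the
#' entity it represents is present.
#'
#' @param v Numeric vector, or matrix with capsules in rows.
#' @return Scalar norm, or vector of norms for a matrix input.
#' @export
capsule_length <- function(v) {
  if (!all(is.finite(v))) stop("capsule_length(): non-finite input")
  if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
}

#' Margin-loss parameters
#'
#' @param m_plus Positive-class margin, default 0.9.
#' @param m_minus Negative-class margin, default 0.1.
#' @param lam Down-weighting of absent-class terms, default 0.5.
#' @return List of parameters, validated.
#' @export
margin_loss_params <- function(m_plus = 0.9, m_minus = 0.1, lam = 0.5) {
  stopifnot(m_plus > 0, m_plus < 1, m_minus > 0, m_minus < 1, lam >= 0)
  list(m_plus = m_plus, m_minus = m_minus, lam = lam)
}

#' Margin loss on capsule lengths
#'
#' Per-class hinge-squared loss on the lengths of the output capsules:
#' `L_k = T_k max(0, m+ - |v_k|)^2 + lam (1 - T_k) max(0, |v_k| - m-)^2`,
#' summed over classes. Present classes are pushed above `m+`, absent ones
#' below `m-`.
#'
#' @param lengths Non-negative capsule lengths, one per class.
#' @param targets Binary vector `T_k` (1 = class present).
#' @param params List from [margin_loss_params()].
#' @return Scalar total loss.
#' @export
margin_loss <- function(lengths, targets, params = margin_loss_params()) {
  stopifnot(length(lengths) == length(targets), all(lengths >= 0),
            all(targets %in% c(0, 1)))
  pos <- pmax(0, params$m_plus - lengths)^2
  neg <- pmax(0, lengths - params$m_minus)^2
  sum(targets * pos + params$lam * (1 - targets) * neg)
}
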