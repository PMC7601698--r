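# Adversarial objectives and the analytic quantities used to cross-check
# them: the original minimax value, the least-squares losses used for
# training, the optimal-discriminator form and the Jensen-Shannon identity
# linking the generator cost to JSD(p_data || p_g).

#' Original GAN minimax value
#'
#' `E[log d_real] + E[log(1 - d_fake)]` over the supplied score vectors.
#' Scores exactly at 0 or 1 are clamped to `[eps, 1 - eps]` with
#' `eps = 1e-7` (and a warning) to keep the logs finite.
#'
#' @param d_real,d_fake Discriminator scores in `(0, 1)`.
#' @return Scalar value (always `<= 0`).
#' @export
gan_value <- function(d_real, d_fake) {
  eps <- 1e-7
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1)) {
    warning("gan_value(): scores clamped to (0, 1) with eps = 1e-7")
    d_real <- pmin(pmax(d_real, eps), 1 - eps)
    d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  }
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Least-squares discriminator loss
#'
#' `0.5 E[(d_real - 1)^2] + 0.5 E[d_fake^2]`: real samples are pulled to the
#' target code 1 and generated samples to 0.
#'
#' @param d_real,d_fake Finite discriminator scores.
#' @return Scalar loss, `>= 0`.
#' @export
ls_discriminator_loss <- function(d_real, d_fake) {
  stopifnot(all(is.finite(d_real)), all(is.finite(d_fake)))
  0.5 * mean((d_real - 1)^2) + 0.5 * mean(d_fake^2)
}

#' Least-squares generator loss
#'
#' `0.5 E[(d_fake - 1)^2]`: the generator pushes the discriminator's score
#' on generated samples towards the real-target code 1.
#'
#' @param d_fake Finite discriminator scores on generated samples.
#' @return Scalar loss, `>= 0`.
#' @export
ls_generator_loss <- function(d_fake) {
  stopifnot(all(is.finite(d_fake)))
  0.5 * mean((d_fake - 1)^2)
}

#' Optimal discriminator for fixed generator
#'
#' `D*(x) = p_data(x) / (p_data(x) + p_g(x))`, evaluated elementwise on a
#' pair of densities over a common support.
#'
#' @param p_data,p_g Non-negative density values at the same points.
#' @return Values in `[0, 1]`.
#' @export
optimal_discriminator <- function(p_data, p_g) {
  stopifnot(length(p_data) == length(p_g), all(p_data >= 0), all(p_g >= 0))
  tot <- p_data + p_g
  if (any(tot == 0)) stop("optimal_discriminator(): both densities zero at some point")
  p_data / tot
}

#' Generator cost at the optimal discriminator
#'
#' `C(G) = -log 4 + 2 JSD(p_data || p_g)`: with the discriminator optimal,
#' the original GAN generator minimises the Jensen-Shannon divergence to the
#' data distribution, reaching `-log 4` at equality.
#'
#' @param jsd Jensen-Shannon divergence, `>= 0` (nats).
#' @return Scalar cost.
#' @export
generator_cost_from_jsd <- function(jsd) {
  if (any(jsd < 0)) stop("generator_cost_from_jsd(): jsd must be >= 0")
  -log(4) + 2 * jsd
}

#' Jensen-Shannon divergence between discrete distributions
#'
#' `JSD(p || q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, in nats.
#'
#' @param p,q Probability vectors over the same support.
#' @return Scalar in `[0, log 2]`.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q),
            abs(sum(p) - 1) < 1e-8, abs(sum(q) - 1) < 1e-8)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}
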