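# Monte-Carlo angular loss: the expected angle between a Gaussian-distributed
# readout y ~ N(mu_hat, Sigma_hat) and the unit ground-truth direction t,
# E[arccos(y . t / |y|)], estimated with reparameterized samples
# y = mu_hat + L z (Sigma_hat = L L^T). The estimator is unbiased and
# differentiable w.r.t. (mu_hat, Sigma_hat); the arccos argument is clamped
# away from +/-1 for gradient stability.

ARC_CLAMP <- 1e-7

# Cholesky of a jittered 2x2 covariance; clamps the correlation if the
# jittered matrix is still numerically indefinite.
.chol2 <- function(S, jitter) {
  a <- S[1, 1] + jitter
  c2 <- S[2, 2] + jitter
  b <- S[1, 2]
  bmax <- 0.999999 * sqrt(a * c2)
  b <- max(min(b, bmax), -bmax)
  l11 <- sqrt(a)
  l21 <- b / l11
  l22 <- sqrt(c2 - b^2 / a)
  c(l11 = l11, l21 = l21, l22 = l22, a = a, b = b, c = c2)
}

# loss and gradients for one example. z: n x 2 standard-normal draws.
.angular_loss_1 <- function(mu_hat, Sigma_hat, theta, z, jitter,
                            grad = TRUE) {
  tv <- c(cos(theta), sin(theta))
  L <- .chol2(Sigma_hat, jitter)
  y1 <- mu_hat[1] + L["l11"] * z[, 1]
  y2 <- mu_hat[2] + L["l21"] * z[, 1] + L["l22"] * z[, 2]
  r <- sqrt(y1^2 + y2^2)
  r <- pmax(r, 1e-12)
  u <- (y1 * tv[1] + y2 * tv[2]) / r
  ucl <- pmin(pmax(u, -1 + ARC_CLAMP), 1 - ARC_CLAMP)
  loss <- mean(acos(ucl))
  if (!grad) return(list(loss = loss))
  inside <- (u > -1 + ARC_CLAMP) & (u < 1 - ARC_CLAMP)
  dldu <- ifelse(inside, -1 / sqrt(1 - ucl^2), 0)
  dy1 <- dldu * (tv[1] / r - u * y1 / r^2)
  dy2 <- dldu * (tv[2] / r - u * y2 / r^2)
  n <- length(dy1)
  dmu <- c(mean(dy1), mean(dy2))
  dl11 <- mean(dy1 * z[, 1])
  dl21 <- mean(dy2 * z[, 1])
  dl22 <- mean(dy2 * z[, 2])
  # backward through the 2x2 Cholesky
  a <- L["a"]; b <- L["b"]
  l11 <- L["l11"]; l21 <- L["l21"]; l22 <- L["l22"]
  da <- dl11 / (2 * l11) - dl21 * l21 / (2 * a) +
    dl22 * b^2 / (2 * a^2 * l22)
  db <- dl21 / l11 - dl22 * (b / a) / l22
  dc <- dl22 / (2 * l22)
  dSig <- matrix(c(da, db / 2, db / 2, dc), 2, 2)
  list(loss = loss, dmu = dmu, dSig = unname(dSig))
}

#' Monte-Carlo angular loss
#'
#' Unbiased reparameterized Monte-Carlo estimate of the expected angular
#' error \eqn{E[\arccos(y \cdot t / |y|)]} of a Gaussian readout
#' \eqn{y \sim N(\hat\mu, \hat\Sigma)} against the unit direction vector of
#' `theta_true`. Values lie in `[0, pi]` radians.
#'
#' @param mu_hat Readout mean, length 2.
#' @param Sigma_hat Readout covariance, 2 x 2 PSD (jittered before the
#'   Cholesky factorization).
#' @param theta_true True direction (rad).
#' @param n_samples Monte-Carlo samples (>= 1), default 32.
#' @param jitter Diagonal jitter added before factorization, default `1e-6`.
#' @param z Optional `n_samples x 2` matrix of standard-normal draws (for
#'   common random numbers); drawn internally if `NULL`.
#' @return Scalar loss (radians).
#' @examples
#' angular_loss(c(1, 0), diag(0, 2), 0)      # perfect alignment: 0
#' angular_loss(c(-1, 0), diag(0, 2), 0)     # antipodal: pi
#' @export
angular_loss <- function(mu_hat, Sigma_hat, theta_true, n_samples = 32,
                         jitter = 1e-6, z = NULL) {
  stopifnot(length(mu_hat) == 2, all(dim(as.matrix(Sigma_hat)) == c(2, 2)),
            n_samples >= 1)
  if (is.null(z)) z <- matrix(stats::rnorm(2 * n_samples), n_samples, 2)
  .angular_loss_1(mu_hat, as.matrix(Sigma_hat), theta_true, z, jitter,
                  grad = FALSE)$loss
}

# softmax cross-entropy on logits (readout means); labels in 1..K.
# returns loss and dlogits (B x K)
.xent_loss <- function(logits, labels) {
  B <- nrow(logits)
  m <- apply(logits, 1L, max)
  ez <- exp(logits - m)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(B), labels)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / B)
}

# clip the global gradient norm (guards against the heavy-tailed samples the
# angular loss produces when a readout draw lands near the origin)
.clip_grads <- function(grads, max_norm) {
  sq <- function(x) {
    if (is.null(x)) return(0)
    if (is.list(x)) return(sum(vapply(x, sq, numeric(1))))
    sum(x^2)
  }
  nrm <- sqrt(sq(grads))
  if (!is.finite(nrm) || nrm <= max_norm) return(grads)
  scale_by <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) return(lapply(x, scale_by))
    x * (max_norm / nrm)
  }
  scale_by(grads)
}

# AdamW update; params and grads are nested lists of numeric arrays with the
# same shape. Decoupled weight decay as in the reference algorithm.
.adamw_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0)
}

.adamw_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, weight_decay = 1e-2) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (i in seq_along(p)) {
        if (is.null(p[[i]]) || is.null(g[[i]])) next
        r <- step(p[[i]], g[[i]], m[[i]], v[[i]])
        out$p[[i]] <- r$p; out$m[[i]] <- r$m; out$v[[i]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  r <- step(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
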