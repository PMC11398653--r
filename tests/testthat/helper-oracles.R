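# Independent oracles used across the suite. All are built from base R /
# pracma quadrature or brute-force simulation, never from the package's own
# evaluation path.

# g(x) = e^{x^2} int_{-inf}^x e^{-u^2} du via the normal CDF
g_oracle <- function(x) exp(x^2 + pnorm(sqrt(2) * x, log.p = TRUE) +
                              0.5 * log(pi))

# h(x) by adaptive quadrature of e^{-u^2} g(u)^2 (log-space integrand)
h_oracle <- function(x) {
  vapply(x, function(z) {
    exp(z^2) * stats::integrate(function(u)
      exp(u^2 + 2 * pnorm(sqrt(2) * u, log.p = TRUE) + log(pi)),
      -Inf, z, rel.tol = 1e-11)$value
  }, numeric(1))
}

# Monte-Carlo single LIF neuron driven by white-noise current; returns
# long-window count statistics and their standard errors.
lif_mc_oracle <- function(mu, sigma, T_ms = 4e5, dt = 0.005, win = 2000,
                          params = lif_params()) {
  cnt <- momentcov:::cpp_lif_single(mu, sigma, as.integer(T_ms / dt), dt,
                                    as.integer(win / dt), params$L,
                                    params$V_th, params$V_res, params$T_ref)
  n <- length(cnt)
  list(mu = mean(cnt) / win, se_mu = sd(cnt) / win / sqrt(n),
       var = var(cnt) / win, se_var = var(cnt) / win * sqrt(2 / (n - 1)))
}

# dense 2-D quadrature of the expected angular error of y ~ N(mu, Sigma)
# against the unit vector at angle theta
angular_loss_quad <- function(mu, Sigma, theta) {
  tv <- c(cos(theta), sin(theta))
  ch <- chol(Sigma)
  f <- function(z1, z2) {
    y1 <- mu[1] + ch[1, 1] * z1
    y2 <- mu[2] + ch[1, 2] * z1 + ch[2, 2] * z2
    r <- sqrt(y1^2 + y2^2)
    u <- pmin(pmax((y1 * tv[1] + y2 * tv[2]) / pmax(r, 1e-12), -1), 1)
    acos(u) * exp(-(z1^2 + z2^2) / 2) / (2 * pi)
  }
  pracma::integral2(f, -8, 8, -8, 8, reltol = 1e-8)$Q
}

# 1-D mutual information of an equiprobable binary Gaussian channel
# N(+m, s^2) vs N(-m, s^2), by adaptive quadrature
binary_gaussian_mi <- function(m, s) {
  py <- function(y) 0.5 * dnorm(y, m, s) + 0.5 * dnorm(y, -m, s)
  hy <- stats::integrate(function(y) {
    p <- py(y)
    ifelse(p > 0, -p * log(p), 0)
  }, -Inf, Inf, rel.tol = 1e-10)$value
  hy - 0.5 * log(2 * pi * exp(1) * s^2)
}

# circular helpers
wrap_angle <- function(x) atan2(sin(x), cos(x))

# ISI-based oracle: for the white-noise-driven LIF the inter-spike intervals
# are i.i.d. (memoryless reset), so the count statistics follow renewal
# theory: rate = 1/E[ISI], variance rate = Var[ISI]/E[ISI]^3. This avoids
# the O(1)/window boundary bias of windowed count estimators, which dominates
# for near-regular spike trains.
lif_isi_oracle <- function(mu, sigma, T_ms = 2.4e5, dt = 0.01,
                           params = lif_params()) {
  cnt <- momentcov:::cpp_lif_single(mu, sigma, as.integer(T_ms / dt), dt,
                                    as.integer(0.1 / dt), params$L,
                                    params$V_th, params$V_res, params$T_ref)
  tk <- which(cnt > 0) * 0.1
  n <- length(tk)
  if (n < 2) return(list(n = n, mu = n / T_ms, se_mu = sqrt(max(n, 1)) / T_ms,
                         var = NA, se_var = NA))
  isi <- diff(tk)
  rate <- 1 / mean(isi)
  se_rate <- rate * sd(isi) / mean(isi) / sqrt(length(isi))
  folds <- cut(seq_along(isi), 10, labels = FALSE)
  est <- tapply(isi, folds, function(x) var(x) / mean(x)^3)
  list(n = n, mu = rate, se_mu = se_rate,
       var = var(isi) / mean(isi)^3, se_var = sd(est) / sqrt(10))
}
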