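# Moment activation of the LIF neuron: closed-form maps from the mean and
# variance of the synaptic current to the mean, variance and pairwise
# correlation of the output spike counts, derived from the first-passage-time
# statistics of the Ornstein-Uhlenbeck membrane process:
#
#   mu    = 1 / (T_ref + (2/L) \int_{I_lb}^{I_ub} g(x) dx)
#   sigma^2 = (8/L^2) mu^3 \int_{I_lb}^{I_ub} h(x) dx
#   rho_ij = chi_i chi_j rhobar_ij,  chi = (sbar/sigma) dmu/dmubar
#
# with bounds I_ub = (V_th L - mubar)/(sbar sqrt(L)) and
# I_lb = (V_res L - mubar)/(sbar sqrt(L)). All first derivatives (and the
# second derivative of mu needed to backpropagate through the correlation
# gain) are computed analytically from g' = 2xg + 1 and h' = 2xh + g^2.

# rates below this (sp/ms) are treated as exact silence
RATE_TINY <- 1e-14

.recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  list(rep_len(a, n), rep_len(b, n))
}

#' Integration bounds of the moment activation
#'
#' Returns the standardized integration bounds of the LIF first-passage
#' integrals, \eqn{I_{ub} = (V_{th} L - \bar\mu)/(\bar\sigma \sqrt L)} and
#' \eqn{I_{lb} = (V_{res} L - \bar\mu)/(\bar\sigma \sqrt L)}.
#'
#' @param mu_bar Mean input current (mV/ms), vector.
#' @param sigma_bar Input current std on the per-sqrt(ms) scale (mV/sqrt(ms)),
#'   vector; must exceed the noise floor `1e-3` (below it the caller must use
#'   the noise-free branch).
#' @param params A [lif_params()] object.
#' @return List with elements `I_lb` and `I_ub` (`I_ub > I_lb` always).
#' @export
integration_bounds <- function(mu_bar, sigma_bar, params = lif_params()) {
  if (any(sigma_bar <= SIGMA_FLOOR))
    stop("integration_bounds: sigma_bar at/below the noise floor; ",
         "use the noise-free branch", call. = FALSE)
  sqL <- sqrt(params$L)
  list(I_lb = (params$V_res * params$L - mu_bar) / (sigma_bar * sqL),
       I_ub = (params$V_th * params$L - mu_bar) / (sigma_bar * sqL))
}

# Noise-free LIF rate and derivatives (sigma_bar ~ 0). Superthreshold drive
# (mu_bar > V_th L) fires deterministically with ISI
# T_ref + (1/L) log((mu - V_res L)/(mu - V_th L)); otherwise silent.
.ma_noisefree <- function(m, params) {
  L <- params$L
  a <- params$V_res * L
  b <- params$V_th * L
  n <- length(m)
  mu <- k <- dk_dm <- numeric(n)
  sup <- m > b
  if (any(sup)) {
    ms <- m[sup]
    mu0 <- 1 / (params$T_ref + (1 / L) * log((ms - a) / (ms - b)))
    q <- 1 / (ms - b) - 1 / (ms - a)
    k0 <- mu0^2 * q / L
    qp <- -1 / (ms - b)^2 + 1 / (ms - a)^2
    mu[sup] <- mu0
    k[sup] <- k0
    dk_dm[sup] <- 2 * mu0 * k0 * q / L + mu0^2 * qp / L
  }
  list(mu = mu, sigma = numeric(n), k = k,
       dmu_ds = numeric(n), dsig_dm = numeric(n), dsig_ds = numeric(n),
       dk_dm = dk_dm, dk_ds = numeric(n))
}

# Vectorized moment-activation core with analytic partials.
# m: mean input current, s: input current std. Returns mu, sigma,
# k = dmu/dm (the correlation gain), and the partial derivatives needed for
# backpropagation. All outputs are zero (with zero gradients) for silent
# neurons.
.ma_core <- function(m, s, params = lif_params()) {
  stopifnot(length(m) == length(s))
  n <- length(m)
  out <- list(mu = numeric(n), sigma = numeric(n), k = numeric(n),
              dmu_ds = numeric(n), dsig_dm = numeric(n),
              dsig_ds = numeric(n), dk_dm = numeric(n), dk_ds = numeric(n))
  if (n == 0L) return(out)
  nf <- s <= SIGMA_FLOOR
  if (any(nf)) {
    r <- .ma_noisefree(m[nf], params)
    for (f in names(out)) out[[f]][nf] <- r[[f]]
  }
  if (!any(!nf)) return(out)

  idx <- which(!nf)
  m <- m[idx]; s <- s[idx]
  L <- params$L; sqL <- sqrt(L)
  Iu <- (params$V_th * L - m) / (s * sqL)
  Il <- (params$V_res * L - m) / (s * sqL)
  live <- Il < DAWSON_X_HI
  if (any(live)) {
    j <- idx[live]
    m <- m[live]; s <- s[live]
    Iu <- pmin(Iu[live], DAWSON_X_HI)   # tail beyond 10 only deepens silence
    Il <- Il[live]

    gu <- .g_raw(Iu); gl <- .g_raw(Il)
    hu <- dawson_h(Iu); hl <- dawson_h(Il)
    G <- .Fg(Iu) - .Fg(Il)
    H <- pmax(.Fh(Iu) - .Fh(Il), 0)

    c1 <- 2 / L
    Tm <- params$T_ref + c1 * G
    mu <- 1 / Tm
    ok <- mu > RATE_TINY
    if (any(ok)) {
      jj <- j[ok]
      m <- m[ok]; s <- s[ok]; Iu <- Iu[ok]; Il <- Il[ok]
      gu <- gu[ok]; gl <- gl[ok]; hu <- hu[ok]; hl <- hl[ok]
      G <- G[ok]; H <- H[ok]; mu <- mu[ok]

      pm <- -1 / (s * sqL)              # dI/dm (same for both bounds)
      dG_dm <- pm * (gu - gl)
      dG_ds <- -(gu * Iu - gl * Il) / s
      k  <- -c1 * mu^2 * dG_dm          # dmu/dm > 0
      mus <- -c1 * mu^2 * dG_ds

      c2 <- 8 / L^2
      sig2 <- c2 * mu^3 * H
      sig <- sqrt(sig2)
      dH_dm <- pm * (hu - hl)
      dH_ds <- -(hu * Iu - hl * Il) / s
      pos <- sig > 0
      dsig_dm <- dsig_ds <- numeric(length(sig))
      dsig_dm[pos] <- sig[pos] *
        (1.5 * k[pos] / mu[pos] + 0.5 * dH_dm[pos] / H[pos])
      dsig_ds[pos] <- sig[pos] *
        (1.5 * mus[pos] / mu[pos] + 0.5 * dH_ds[pos] / H[pos])

      # second derivatives of mu for the correlation-gain backward pass
      gpu <- 2 * Iu * gu + 1
      gpl <- 2 * Il * gl + 1
      dg_dm <- pm * (gpu - gpl)              # d(gu - gl)/dm
      dg_ds <- -(gpu * Iu - gpl * Il) / s
      dpm_ds <- -pm / s
      dk_dm <- -c1 * (2 * mu * k * pm * (gu - gl) + mu^2 * pm * dg_dm)
      dk_ds <- -c1 * (2 * mu * mus * pm * (gu - gl) +
                        mu^2 * dpm_ds * (gu - gl) + mu^2 * pm * dg_ds)

      out$mu[jj] <- mu
      out$sigma[jj] <- sig
      out$k[jj] <- k
      out$dmu_ds[jj] <- mus
      out$dsig_dm[jj] <- dsig_dm
      out$dsig_ds[jj] <- dsig_ds
      out$dk_dm[jj] <- dk_dm
      out$dk_ds[jj] <- dk_ds
    }
  }
  out
}

#' Mean firing rate map of the moment activation
#'
#' Maps the mean and std of a neuron's synaptic current to its stationary
#' mean firing rate. Continuous in both arguments; below the noise floor on
#' `sigma_bar` the noise-free closed-form LIF rate is returned.
#'
#' @inheritParams integration_bounds
#' @param sigma_bar Input current std (mV/sqrt(ms)), non-negative.
#' @return Firing rate (sp/ms), in `[0, 1/T_ref)`.
#' @examples
#' phi_mu(2, 1)
#' phi_mu(2, 0)   # noise-free limit, 1/(5 + 20*log(2))
#' @export
phi_mu <- function(mu_bar, sigma_bar, params = lif_params()) {
  stopifnot(all(is.finite(mu_bar)), all(is.finite(sigma_bar)),
            all(sigma_bar >= 0))
  r2 <- .recycle2(mu_bar, sigma_bar)
  mu_bar <- r2[[1]]; sigma_bar <- r2[[2]]
  .ma_core(mu_bar, sigma_bar, params)$mu
}

#' Spike-count std map of the moment activation
#'
#' Maps the mean and std of the synaptic current to the std of the output
#' spike count on the per-unit-time covariance scale
#' (\eqn{\sigma^2 = \lim \mathrm{Var}[n(\Delta t)]/\Delta t}).
#'
#' @inheritParams phi_mu
#' @return Spike-count std (sp/ms^0.5 on the per-unit-time scale), >= 0.
#' @export
phi_sigma <- function(mu_bar, sigma_bar, params = lif_params()) {
  stopifnot(all(is.finite(mu_bar)), all(is.finite(sigma_bar)),
            all(sigma_bar >= 0))
  r2 <- .recycle2(mu_bar, sigma_bar)
  mu_bar <- r2[[1]]; sigma_bar <- r2[[2]]
  .ma_core(mu_bar, sigma_bar, params)$sigma
}

#' Linear perturbation coefficient
#'
#' The gain \eqn{\chi = (\bar\sigma/\sigma)\,\partial\mu/\partial\bar\mu}
#' converting input current correlation into output spike-count correlation
#' around zero correlation. Defined as 0 wherever the output std is 0 (a
#' silent or deterministic neuron transmits no correlation).
#'
#' @inheritParams phi_mu
#' @return Dimensionless coefficient, finite everywhere.
#' @export
chi <- function(mu_bar, sigma_bar, params = lif_params()) {
  stopifnot(all(is.finite(mu_bar)), all(is.finite(sigma_bar)),
            all(sigma_bar >= 0))
  r2 <- .recycle2(mu_bar, sigma_bar)
  mu_bar <- r2[[1]]; sigma_bar <- r2[[2]]
  r <- .ma_core(mu_bar, sigma_bar, params)
  ifelse(r$sigma > 0, sigma_bar / r$sigma * r$k, 0)
}

#' Current moments container
#'
#' Bundles the mean vector and covariance matrix of the total synaptic
#' current of a population.
#'
#' @param mu Mean current per neuron (mV/ms).
#' @param Sigma Covariance of the current (mV^2/ms); must be symmetric with
#'   non-negative diagonal.
#' @return An object of class `current_moments`.
#' @export
current_moments <- function(mu, Sigma) {
  mu <- as.numeric(mu)
  Sigma <- as.matrix(Sigma)
  stopifnot(length(mu) == nrow(Sigma), nrow(Sigma) == ncol(Sigma))
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    stop("current_moments: Sigma must be symmetric", call. = FALSE)
  if (any(diag(Sigma) < -1e-12))
    stop("current_moments: negative variance", call. = FALSE)
  Sigma <- (Sigma + t(Sigma)) / 2
  diag(Sigma) <- pmax(diag(Sigma), 0)
  structure(list(mu = mu, Sigma = Sigma), class = "current_moments")
}

#' Spike moments container
#'
#' Bundles mean firing rates, per-neuron spike-count stds and the spike-count
#' correlation matrix; the covariance is available as
#' \eqn{\Sigma = \sigma\sigma^T \circ \rho}.
#'
#' @param mu Mean firing rates (sp/ms).
#' @param sigma Spike-count stds (per-unit-time scale), >= 0.
#' @param rho Correlation matrix (symmetric, unit diagonal).
#' @return An object of class `spike_moments` with a `Sigma` element.
#' @export
spike_moments <- function(mu, sigma, rho = diag(length(mu))) {
  mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  rho <- as.matrix(rho)
  stopifnot(length(mu) == length(sigma), length(mu) == nrow(rho),
            nrow(rho) == ncol(rho), all(sigma >= 0))
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  structure(list(mu = mu, sigma = sigma, rho = rho,
                 Sigma = tcrossprod(sigma) * rho),
            class = "spike_moments")
}

# Eigenvalue clipping + rescaling to unit diagonal; applied only when the
# linear-perturbation correlation map breaks positive semidefiniteness.
.psd_repair_corr <- function(rho, tol = -1e-10) {
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) >= tol) return(rho)
  lam <- pmax(ev$values, 0)
  S <- ev$vectors %*% (lam * t(ev$vectors))
  d <- sqrt(pmax(diag(S), .Machine$double.eps))
  R <- S / tcrossprod(d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

#' Moment activation
#'
#' Applies the LIF moment activation element-wise to a population: mean rates
#' via [phi_mu()], spike-count stds via [phi_sigma()], and pairwise
#' correlations via the linear perturbation map
#' \eqn{\rho_{ij} = \chi_i \chi_j \bar\rho_{ij}} (unit diagonal). If the
#' linear map produces an indefinite correlation matrix it is repaired by
#' eigenvalue clipping and rescaling to unit diagonal.
#'
#' @param input A [current_moments()] object.
#' @param params A [lif_params()] object.
#' @return A [spike_moments()] object.
#' @examples
#' cm <- current_moments(c(1.5, 1.5), matrix(c(1, .3, .3, 1), 2))
#' moment_activate(cm)$rho
#' @export
moment_activate <- function(input, params = lif_params()) {
  stopifnot(inherits(input, "current_moments"))
  sbar <- sqrt(diag(input$Sigma))
  r <- .ma_core(input$mu, sbar, params)
  ch <- ifelse(r$sigma > 0, sbar / r$sigma * r$k, 0)
  n <- length(input$mu)
  rhobar <- diag(n)
  pos <- sbar > 0
  if (any(pos)) {
    sb <- sbar
    sb[!pos] <- 1
    rhobar <- input$Sigma / tcrossprod(sb)
    rhobar[!pos, ] <- 0
    rhobar[, !pos] <- 0
  }
  rho <- tcrossprod(ch) * rhobar
  diag(rho) <- 1
  rho <- .psd_repair_corr(rho)
  spike_moments(r$mu, r$sigma, rho)
}
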