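# Mutual information between a discrete stimulus and a Gaussian-modeled
# readout, and its breakdown into per-dimension information, signal-similarity
# redundancy, and a noise-correlation residual:
#   I_tot = h(y) - h(y|theta)
#   I_lin = sum_j [h(y_j) - h(y_j|theta)]
#   I_sigsim = h(y_ind) - sum_j h(y_j),  p(y_ind|theta) = prod_j p(y_j|theta)
#   I_cor = I_tot - I_lin - I_sigsim
# Conditional entropies are closed-form Gaussian; marginal (mixture)
# entropies are Monte-Carlo estimates with log-sum-exp mixture densities and
# batched standard errors.

#' Readout ensemble
#'
#' Per-stimulus Gaussian readout models (mean and covariance) with a prior.
#'
#' @param mus List (or matrix, stimuli x dim) of readout means.
#' @param Sigmas List of readout covariance matrices (PSD).
#' @param prior Stimulus prior; defaults to uniform.
#' @return Object of class `readout_ensemble`.
#' @export
readout_ensemble <- function(mus, Sigmas, prior = NULL) {
  if (is.matrix(mus)) mus <- lapply(seq_len(nrow(mus)), function(i) mus[i, ])
  n <- length(mus)
  stopifnot(n >= 1, length(Sigmas) == n)
  d <- length(mus[[1]])
  Sigmas <- lapply(Sigmas, function(S) {
    S <- as.matrix(S)
    stopifnot(nrow(S) == d, ncol(S) == d)
    (S + t(S)) / 2
  })
  if (is.null(prior)) prior <- rep(1 / n, n)
  stopifnot(length(prior) == n, all(prior >= 0),
            abs(sum(prior) - 1) < 1e-8)
  structure(list(mus = mus, Sigmas = Sigmas, prior = prior, dim = d,
                 n_stim = n), class = "readout_ensemble")
}

# jitter singular covariances (with a warning) so entropies stay finite
.ens_regularize <- function(ens, eps = 1e-9) {
  warned <- FALSE
  scale0 <- max(1e-12, max(vapply(ens$Sigmas, function(S) max(abs(S)),
                                  numeric(1))))
  ens$Sigmas <- lapply(ens$Sigmas, function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < eps * scale0) {
      warned <<- TRUE
      S <- S + diag(eps * scale0, nrow(S))
    }
    S
  })
  if (warned) warning("readout ensemble: singular covariance jittered")
  ens
}

.logdet <- function(S) 2 * sum(log(diag(chol(S))))

#' Conditional entropy of the readout
#'
#' Prior-weighted closed-form Gaussian entropies,
#' \eqn{h(y|\theta) = \sum_i p(\theta_i)\,\tfrac12\log\det(2\pi e \Sigma_i)},
#' in nats.
#'
#' @param ens A [readout_ensemble()].
#' @return Scalar conditional entropy (nats).
#' @export
conditional_entropy <- function(ens) {
  stopifnot(inherits(ens, "readout_ensemble"))
  ens <- .ens_regularize(ens)
  d <- ens$dim
  hs <- vapply(ens$Sigmas, function(S)
    0.5 * (d * log(2 * pi * exp(1)) + .logdet(S)), numeric(1))
  sum(ens$prior * hs)
}

# log density of the prior mixture at rows of Y (n x d), via log-sum-exp
.mixture_logdens <- function(ens, Y) {
  n <- nrow(Y)
  d <- ens$dim
  lp <- matrix(-Inf, n, ens$n_stim)
  for (i in seq_len(ens$n_stim)) {
    if (ens$prior[i] == 0) next
    ch <- chol(ens$Sigmas[[i]])
    Z <- forwardsolve(t(ch), t(Y) - ens$mus[[i]])
    lp[, i] <- log(ens$prior[i]) - 0.5 * colSums(Z^2) -
      sum(log(diag(ch))) - d / 2 * log(2 * pi)
  }
  m <- apply(lp, 1L, max)
  m + log(rowSums(exp(lp - m)))
}

.mixture_sample <- function(ens, n) {
  comp <- sample.int(ens$n_stim, n, replace = TRUE, prob = ens$prior)
  Y <- matrix(0, n, ens$dim)
  for (i in unique(comp)) {
    idx <- comp == i
    Y[idx, ] <- MASS::mvrnorm(sum(idx), ens$mus[[i]], ens$Sigmas[[i]]) |>
      matrix(ncol = ens$dim)
  }
  Y
}

#' Monte-Carlo entropy of the readout mixture
#'
#' Estimates \eqn{h(y) = -E[\log p(y)]} with `n_samples` draws from the
#' prior mixture; the standard error comes from 10-fold batching of the
#' samples.
#'
#' @param ens A [readout_ensemble()].
#' @param n_samples Monte-Carlo samples (>= 1000), default 10000.
#' @return List with `h` (nats) and `se`.
#' @export
mixture_entropy <- function(ens, n_samples = 10000) {
  stopifnot(inherits(ens, "readout_ensemble"), n_samples >= 1000)
  ens <- .ens_regularize(ens)
  Y <- .mixture_sample(ens, n_samples)
  ll <- .mixture_logdens(ens, Y)
  folds <- rep_len(seq_len(10L), n_samples)
  fold_means <- -tapply(ll, folds, mean)
  list(h = -mean(ll), se = stats::sd(fold_means) / sqrt(10))
}

#' Total mutual information between stimulus and readout
#'
#' \eqn{I_{tot} = h(y) - h(y|\theta)} (nats), bounded above by the prior
#' entropy.
#'
#' @inheritParams mixture_entropy
#' @return List with `I` (nats) and `se` (from the mixture-entropy MC).
#' @export
info_total <- function(ens, n_samples = 10000) {
  hy <- mixture_entropy(ens, n_samples)
  list(I = hy$h - conditional_entropy(ens), se = hy$se)
}

# marginal (1-D) ensemble for dimension j
.marginal_ens <- function(ens, j) {
  readout_ensemble(lapply(ens$mus, `[`, j),
                   lapply(ens$Sigmas, function(S) S[j, j, drop = FALSE]),
                   ens$prior)
}

# product-of-marginals ensemble (diagonal covariances)
.independent_ens <- function(ens) {
  readout_ensemble(ens$mus,
                   lapply(ens$Sigmas, function(S) diag(diag(S),
                                                       nrow = nrow(S))),
                   ens$prior)
}

#' Information breakdown of the readout
#'
#' Decomposes [info_total()] into `I_lin` (sum of per-dimension marginal
#' informations), `I_sigsim` (redundancy from tuning-curve overlap, computed
#' from the product-of-marginals population), and the residual `I_cor`
#' attributable to noise correlations; the three parts sum to `I_tot`
#' exactly by construction. Independent Monte-Carlo streams are used for
#' each entropy.
#'
#' @inheritParams mixture_entropy
#' @return Object of class `info_breakdown`: `I_tot`, `I_lin`, `I_sigsim`,
#'   `I_cor` (nats) with standard errors `se_*`.
#' @export
info_breakdown <- function(ens, n_samples = 10000) {
  stopifnot(inherits(ens, "readout_ensemble"), ens$dim >= 2)
  hy <- mixture_entropy(ens, n_samples)
  hcond <- conditional_entropy(ens)
  I_tot <- hy$h - hcond

  hj <- lapply(seq_len(ens$dim), function(j) {
    me <- .marginal_ens(ens, j)
    h <- mixture_entropy(me, n_samples)
    list(h = h$h, se = h$se, hcond = conditional_entropy(me))
  })
  I_lin <- sum(vapply(hj, function(x) x$h - x$hcond, numeric(1)))
  se_lin <- sqrt(sum(vapply(hj, function(x) x$se^2, numeric(1))))

  hind <- mixture_entropy(.independent_ens(ens), n_samples)
  I_sigsim <- hind$h - sum(vapply(hj, `[[`, numeric(1), "h"))
  I_cor <- I_tot - I_lin - I_sigsim
  structure(list(I_tot = I_tot, I_lin = I_lin, I_sigsim = I_sigsim,
                 I_cor = I_cor, se_tot = hy$se, se_lin = se_lin,
                 se_sigsim = sqrt(hind$se^2 + se_lin^2),
                 n_samples = n_samples),
            class = "info_breakdown")
}

#' @export
print.info_breakdown <- function(x, ...) {
  cat(sprintf(
    "information breakdown (nats): I_tot %.3f  I_lin %.3f  I_sigsim %.3f  I_cor %.3f\n",
    x$I_tot, x$I_lin, x$I_sigsim, x$I_cor))
  invisible(x)
}

#' Convergence time of the information curve
#'
#' First readout window at which the total information is within `tol` nats
#' of the prior entropy `H_theta`.
#'
#' @param info_vs_window Numeric vector of `I_tot` per window (nats).
#' @param H_theta Prior entropy (nats).
#' @param tol Tolerance (nats), default 0.1.
#' @return Index of the first window meeting the criterion, or `NA` if none.
#' @export
convergence_time <- function(info_vs_window, H_theta, tol = 0.1) {
  hit <- which(abs(info_vs_window - H_theta) < tol)
  if (!length(hit)) NA_integer_ else hit[1L]
}

#' Readout ensemble from spiking-network trials
#'
#' Builds a per-stimulus Gaussian readout model from simulated trials: for
#' each stimulus, the empirical mean and covariance of the readout at the
#' given window length.
#'
#' @param readouts List over stimuli of trials x dim readout matrices.
#' @param prior Optional prior (default uniform).
#' @return A [readout_ensemble()].
#' @export
ensemble_from_trials <- function(readouts, prior = NULL) {
  readout_ensemble(lapply(readouts, colMeans),
                   lapply(readouts, stats::cov), prior)
}
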