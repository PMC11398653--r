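# Synthetic-data generators: the two-channel (odor-like) discrimination task
# whose classes differ only in the sign of the rate correlation, surrogate
# "feature-map" moment datasets with tunable covariance/mean separability
# (standing in for CNN feature maps of natural images, which are out of
# scope), and a deterministic grating evaluation battery.

#' Two-channel correlated-rate discrimination task
#'
#' Generates per-bin rate traces for two sensory channels whose means are
#' identical across classes while the per-bin rate correlation is `+rho` for
#' class `s = +1` and `-rho` for `s = -1`: the class is invisible to the mean
#' firing rates by construction and lives entirely in the signal covariance.
#' Per-bin rates are a correlated bivariate Gaussian rectified at a small
#' positive floor.
#'
#' @param n Number of stimuli (split evenly between classes, alternating).
#' @param rho_magnitude Rate correlation magnitude in `(0, 1]`.
#' @param n_bins Number of rate bins per stimulus.
#' @param dt Bin width (ms).
#' @param base_rate Mean rate per channel (sp/ms).
#' @param rate_sd Per-bin rate fluctuation SD (sp/ms).
#' @param seed Optional seed.
#' @return List with `stimuli` (each with `rates` (2 x n_bins), `label` in
#'   `{-1, 1}`) and the generator settings.
#' @export
make_odor_task <- function(n, rho_magnitude = 0.6, n_bins = 400, dt = 1,
                           base_rate = 1, rate_sd = 0.5, seed = NULL) {
  stopifnot(n >= 1, rho_magnitude >= 0, rho_magnitude <= 1, n_bins >= 2,
            base_rate > 0, rate_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  labels <- rep_len(c(1L, -1L), n)
  stimuli <- lapply(seq_len(n), function(i) {
    rho <- rho_magnitude * labels[i]
    S <- rate_sd^2 * matrix(c(1, rho, rho, 1), 2)
    rates <- t(MASS::mvrnorm(n_bins, rep(base_rate, 2), S))
    rates <- pmax(rates, 1e-3)
    list(rates = rates, label = labels[i])
  })
  list(stimuli = stimuli, labels = labels, rho_magnitude = rho_magnitude,
       dt = dt, base_rate = base_rate, rate_sd = rate_sd)
}

#' Odor-task moments as a classifier dataset
#'
#' Encodes each two-channel stimulus with [encode_two_channel()] and relabels
#' classes to `1:2` for [train_classifier()].
#'
#' @param task Output of [make_odor_task()].
#' @return Dataset list with `examples` (`mu`, `Sigma`, `label`) and `K = 2`.
#' @export
odor_task_moments <- function(task) {
  examples <- lapply(task$stimuli, function(s) {
    enc <- encode_two_channel(s$rates, task$dt)
    list(mu = enc$mu, Sigma = enc$Sigma,
         label = if (s$label > 0) 1L else 2L)
  })
  list(examples = examples, K = 2L, C = 2L)
}

#' Surrogate feature-map moment dataset
#'
#' Builds class-conditional channel-moment examples emulating flattened
#' feature maps: per class, a covariance template (shared base plus a
#' class-specific low-rank perturbation scaled by `covariance_separability`)
#' and a mean offset scaled by `mean_separability`. Each example is a
#' rectified Gaussian channel sequence of length `L_seq` whose empirical
#' mean and (signal + Poisson-noise) covariance form the input moments, so
#' examples scatter around their class templates with `~ 1/sqrt(L_seq)`
#' fluctuations.
#'
#' @param n_per_class Examples per class.
#' @param K Number of classes.
#' @param C Number of channels (>= 2); default 64.
#' @param covariance_separability Scale of the class-specific covariance
#'   perturbation (>= 0).
#' @param mean_separability Scale of the class mean offsets (>= 0).
#' @param L_seq Sequence length per example; default 784 (a 28 x 28 feature
#'   map flattened).
#' @param base_rate Baseline channel mean (sp/ms).
#' @param rate_sd Baseline channel fluctuation SD.
#' @param seed Optional seed.
#' @param templates Class templates from a previous call (to generate a test
#'   split of the same classes); freshly drawn when `NULL`.
#' @return Dataset list with `examples` (`mu` (C), `Sigma` (C x C), `label`
#'   in `1..K`), `K`, `C`, and the class templates.
#' @export
make_feature_moments <- function(n_per_class, K, C = 64,
                                 covariance_separability = 1,
                                 mean_separability = 0, L_seq = 784,
                                 base_rate = 1, rate_sd = 0.5,
                                 seed = NULL, templates = NULL) {
  stopifnot(n_per_class >= 1, K >= 2, C >= 2,
            covariance_separability >= 0, mean_separability >= 0,
            L_seq >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(templates)) {
    # shared base covariance: weak random channel correlations around a band
    A <- matrix(stats::rnorm(C * C, sd = 0.15 / sqrt(C)), C)
    base_corr <- diag(C) + (A + t(A))
    base_cov <- rate_sd^2 * base_corr
    templates <- lapply(seq_len(K), function(k) {
      q <- stats::rnorm(C); q <- q / sqrt(sum(q^2))
      cls_cov <- base_cov +
        covariance_separability * rate_sd^2 * tcrossprod(q)
      ev <- eigen(cls_cov, symmetric = TRUE)
      cls_cov <- ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
      mu_k <- base_rate + mean_separability * stats::rnorm(C, sd = rate_sd)
      list(mu = mu_k, cov = (cls_cov + t(cls_cov)) / 2)
    })
  }
  examples <- list()
  for (k in seq_len(K)) {
    tpl <- templates[[k]]
    ch <- t(chol(tpl$cov + diag(1e-10, C)))
    for (i in seq_len(n_per_class)) {
      Z <- ch %*% matrix(stats::rnorm(C * L_seq), C)
      seq_rates <- pmax(tpl$mu + Z, 0)
      enc <- encode_two_channel(seq_rates, dt = 1)
      examples[[length(examples) + 1L]] <-
        list(mu = enc$mu, Sigma = enc$Sigma, label = k)
    }
  }
  ord <- sample(length(examples))
  list(examples = examples[ord], K = K, C = C, templates = templates,
       L_seq = L_seq)
}

#' Grating evaluation battery
#'
#' Deterministic grid of `(theta, contrast)` probe stimuli with their
#' analytic encodings, directions uniform on `[-pi, pi)`.
#'
#' @param array Detector array.
#' @param directions Number of directions (>= 2), default 50.
#' @param contrasts Contrast levels.
#' @param ... Passed to [grating_stimulus()].
#' @return List with `theta`, `contrasts`, and `stimuli[[ci]][[di]]`
#'   encodings.
#' @export
make_grating_suite <- function(array, directions = 50, contrasts = 0.8,
                               ...) {
  stopifnot(directions >= 2)
  theta <- seq(-pi, pi, length.out = directions + 1L)[-(directions + 1L)]
  stimuli <- lapply(contrasts, function(cc)
    lapply(theta, function(th)
      encode_grating(grating_stimulus(cc, th, ...), array)))
  list(theta = theta, contrasts = contrasts, stimuli = stimuli)
}
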