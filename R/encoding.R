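# Analytic covariance encoders: deterministic rate traces of intensity and
# change detectors viewing a drifting grating, and the closed-form input
# moments they induce on spike counts observed over a short window. Direction
# is carried entirely by the covariance (the mean is direction-independent);
# opposite motion directions are disambiguated by the intensity-change
# cross-covariance.

#' Drifting grating stimulus
#'
#' Parameters of a sinusoidal grating \eqn{I(x,t) = 1 + c\cos(k \cdot x -
#' \omega t)} drifting along its wave vector, together with the detector
#' gains.
#'
#' @param contrast Contrast `c` in `[0, 1]`.
#' @param theta Motion direction (rad); the wave vector is
#'   `k_norm * (cos theta, sin theta)`.
#' @param k_norm Spatial frequency `|k|` (rad per unit length); default `5*pi`.
#' @param omega Temporal angular frequency (rad/ms); default 1. The product
#'   `contrast * omega` must not exceed 1 or the change-detector rate would go
#'   negative.
#' @param alpha Intensity-detector gain (sp/ms).
#' @param beta Change-detector gain (sp/ms).
#' @return An object of class `grating_stimulus`.
#' @examples
#' grating_stimulus(contrast = 0.8, theta = 0.06)
#' @export
grating_stimulus <- function(contrast, theta, k_norm = 5 * pi, omega = 1,
                             alpha = 1, beta = 1) {
  stopifnot(is.numeric(contrast), length(contrast) == 1L,
            contrast >= 0, contrast <= 1)
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  stopifnot(k_norm > 0, omega > 0, alpha > 0, beta > 0)
  if (contrast * omega > 1)
    stop("grating_stimulus: contrast * omega > 1 gives negative change-",
         "detector rates", call. = FALSE)
  structure(list(contrast = contrast, theta = theta, k_norm = k_norm,
                 omega = omega, alpha = alpha, beta = beta,
                 k = k_norm * c(cos(theta), sin(theta))),
            class = "grating_stimulus")
}

#' Deterministic detector rate traces for a grating
#'
#' Instantaneous Poisson rates of the paired detectors: intensity channel
#' \eqn{\alpha[1 + c\cos(k \cdot x - \omega t)]} and change channel
#' \eqn{\beta[1 - c\omega\sin(k \cdot x - \omega t)]}; always non-negative
#' under the constructor's constraint `c * omega <= 1`.
#'
#' @param stim A [grating_stimulus()].
#' @param array A [make_hexagonal_grid()] detector array.
#' @param t_grid Time points (ms).
#' @return Matrix of rates (sp/ms), `2 * n_sites` rows (intensity block then
#'   change block) by `length(t_grid)` columns.
#' @export
grating_rate_traces <- function(stim, array, t_grid) {
  stopifnot(inherits(stim, "grating_stimulus"),
            inherits(array, "detector_array"))
  phase <- drop(array$positions %*% stim$k)       # k . x_i
  arg <- outer(phase, stim$omega * t_grid, `-`)   # k.x - w t
  rbind(stim$alpha * (1 + stim$contrast * cos(arg)),
        stim$beta * (1 - stim$contrast * stim$omega * sin(arg)))
}

#' Encode a grating as sensory-layer input moments
#'
#' Builds the closed-form mean and covariance of the spike counts of the
#' paired intensity/change detectors over an observation window `dt`,
#' expressed on the per-unit-time scale (mean and covariance both divided by
#' `dt`). Blocks: intensity-intensity
#' \eqn{\alpha\delta_{ij} + \tfrac12\alpha^2c^2\cos[k(x_i-x_j)]\Delta t},
#' change-change with gain \eqn{\beta\omega c}, and the antisymmetric
#' intensity-change cross block
#' \eqn{\tfrac12\alpha\beta c^2\omega \sin[k(x_i-x_k)]\Delta t} that encodes
#' the motion direction sign.
#'
#' @inheritParams grating_rate_traces
#' @param dt Observation window (ms), default 1.
#' @return An object of class `encoded_stimulus` with elements `mu` (length
#'   `2N`), `Sigma` (`2N x 2N`, symmetric PSD), `dt`, `stim`, and
#'   `rate_traces(t_grid)`, a closure reproducing the deterministic traces.
#' @export
encode_grating <- function(stim, array, dt = 1) {
  stopifnot(inherits(stim, "grating_stimulus"),
            inherits(array, "detector_array"), dt > 0)
  al <- stim$alpha; be <- stim$beta
  cc <- stim$contrast; om <- stim$omega
  phase <- drop(array$positions %*% stim$k)
  n <- array$n_sites
  dcos <- cos(outer(phase, phase, `-`))
  dsin <- sin(outer(phase, phase, `-`))
  ii <- 0.5 * al^2 * cc^2 * dcos * dt
  kk <- 0.5 * be^2 * cc^2 * om^2 * dcos * dt
  ik <- 0.5 * al * be * cc^2 * om * dsin * dt
  Sigma <- rbind(cbind(ii, ik), cbind(t(ik), kk))
  diag(Sigma) <- diag(Sigma) + rep(c(al, be), each = n)
  mu <- rep(c(al, be), each = n)
  structure(list(mu = mu, Sigma = Sigma, dt = dt, stim = stim,
                 n_sites = n,
                 rate_traces = function(t_grid)
                   grating_rate_traces(stim, array, t_grid)),
            class = "encoded_stimulus")
}

#' Two-channel fluctuating-rate stimulus moments
#'
#' Converts a piecewise-constant two-channel (or multi-channel) rate
#' representation into spike-count moments over the bin width: the mean rate
#' per channel, a diagonal Poisson noise covariance `diag(mu)`, and the
#' cross-time signal covariance
#' \eqn{\Sigma^{signal}_{ij} = \langle(\lambda_{ik}-\mu_i)(\lambda_{jk}-\mu_j)\rangle \Delta t}.
#'
#' @param rates Channels x bins matrix of non-negative per-bin rates (sp/ms).
#' @param dt Bin width (ms).
#' @return List with `mu`, `Sigma_noise`, `Sigma_signal`, and their sum
#'   `Sigma`.
#' @export
encode_two_channel <- function(rates, dt = 1) {
  rates <- as.matrix(rates)
  if (ncol(rates) < 2L)
    stop("encode_two_channel: need at least 2 bins", call. = FALSE)
  stopifnot(all(rates >= 0), dt > 0)
  mu <- rowMeans(rates)
  centered <- rates - mu
  n_bins <- ncol(rates)
  Sigma_signal <- tcrossprod(centered) / n_bins * dt
  Sigma_noise <- diag(mu, nrow = length(mu))
  list(mu = mu, Sigma_noise = Sigma_noise, Sigma_signal = Sigma_signal,
       Sigma = Sigma_noise + Sigma_signal)
}

#' Random direction-task dataset
#'
#' Draws `n` gratings with directions uniform on `[-pi, pi)` and contrasts
#' uniform over `contrast_range`, and encodes each with [encode_grating()].
#'
#' @param n Number of stimuli.
#' @param array Detector array shared by all stimuli.
#' @param contrast_range Length-2 numeric within `[0, 1]`.
#' @param dt Observation window (ms).
#' @param seed Optional integer seed for reproducibility.
#' @param moments_only If `TRUE` (default) skip the rate-trace closures and
#'   return light-weight `(mu, Sigma, theta, contrast)` records.
#' @param ... Further arguments passed to [grating_stimulus()].
#' @return List with `theta`, `contrast` (vectors) and `stimuli` (list of
#'   encodings).
#' @export
direction_dataset <- function(n, array, contrast_range = c(0, 0.8), dt = 1,
                              seed = NULL, moments_only = TRUE, ...) {
  stopifnot(n >= 0, length(contrast_range) == 2L,
            all(contrast_range >= 0), all(contrast_range <= 1))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  theta <- stats::runif(n, -pi, pi)
  contrast <- stats::runif(n, contrast_range[1], contrast_range[2])
  stimuli <- lapply(seq_len(n), function(i) {
    enc <- encode_grating(grating_stimulus(contrast[i], theta[i], ...),
                          array, dt)
    if (moments_only) list(mu = enc$mu, Sigma = enc$Sigma) else enc
  })
  list(theta = theta, contrast = contrast, stimuli = stimuli)
}

# smallest eigenvalue must not be materially negative; clip tiny negatives
.assert_psd <- function(S, rtol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -rtol * max(abs(ev)))
    stop("covariance is not positive semidefinite", call. = FALSE)
  invisible(TRUE)
}
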