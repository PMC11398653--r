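# Population-activity analyses: normalized population spike count, its
# periodogram and autocorrelation, Hilbert-phase Kuramoto synchrony, circular
# readout-error statistics, weight-structure correlation, and an
# energy-distance test of readout Gaussianity.

#' Normalized population spike count
#'
#' Sums binned spike counts over neurons and normalizes:
#' \eqn{D(t) = (R(t) - \langle R\rangle)/\langle R\rangle} with the
#' within-trial mean \eqn{\langle R\rangle}. `mean(D)` is exactly 0.
#'
#' @param counts Neurons x bins matrix of spike counts (one trial, one
#'   layer), or a precomputed population-count vector.
#' @param bin Bin width (ms), kept as metadata.
#' @return Object of class `pop_trace` with `D`, `R`, `mean_R`, `bin`.
#' @export
normalize_pop_count <- function(counts, bin = 1) {
  R <- if (is.matrix(counts)) colSums(counts) else as.numeric(counts)
  mR <- mean(R)
  if (mR <= 0)
    stop("normalize_pop_count: silent population", call. = FALSE)
  structure(list(D = R / mR - 1, R = R, mean_R = mR, bin = bin),
            class = "pop_trace")
}

#' Power spectral density of a normalized population trace
#'
#' Periodogram \eqn{P(f) = |\hat D(f)|^2 / T} with `T` in seconds, so the
#' frequency axis is in Hz and a unit-variance white trace has expected power
#' `~ bin` (Parseval: `sum(P) * df = var(D) * (n-1)/n / bin * 1000`...
#' normalization documented here: `P = |fft(D)|^2 * bin / (1000 * n)` with
#' `df = 1000 / (n * bin)` Hz).
#'
#' @param trace A [normalize_pop_count()] trace (or any list with `D`, `bin`)
#'   or a numeric vector (with `bin` from the argument).
#' @param bin Bin width (ms) when `trace` is a bare vector.
#' @return Data frame with `freq` (Hz, positive frequencies up to Nyquist)
#'   and `power`.
#' @export
pop_psd <- function(trace, bin = 1) {
  D <- if (is.list(trace)) trace$D else as.numeric(trace)
  if (is.list(trace) && !is.null(trace$bin)) bin <- trace$bin
  n <- length(D)
  stopifnot(n >= 2)
  Tsec <- n * bin / 1000
  ft <- stats::fft(D)
  nf <- floor(n / 2)
  idx <- seq_len(nf) + 1L               # drop DC
  data.frame(freq = (idx - 1L) / Tsec,
             power = (Mod(ft[idx]) * bin / 1000)^2 / Tsec)
}

#' Dominant spectral peaks
#'
#' Local maxima of the power spectrum exceeding `thresh` times the median
#' spectral power, sorted by frequency.
#'
#' @param psd Data frame from [pop_psd()].
#' @param thresh Dominance threshold relative to the median power.
#' @return Data frame of peak `freq` and `power` (possibly empty).
#' @export
psd_peaks <- function(psd, thresh = 5) {
  p <- psd$power
  n <- length(p)
  if (n < 3) return(psd[0, ])
  loc <- which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1L
  loc <- loc[p[loc] > thresh * stats::median(p)]
  psd[loc, ]
}

#' Autocorrelation of a normalized population trace
#'
#' \eqn{C(\tau) = \langle D(t) D(t+\tau)\rangle}, normalized so that `C(0)`
#' equals the trace variance (biased estimator, symmetric in lag).
#'
#' @inheritParams pop_psd
#' @param max_lag Largest lag (ms); default a quarter of the record.
#' @return Data frame with `lag` (ms, >= 0) and `C`.
#' @export
pop_autocorr <- function(trace, max_lag = NULL, bin = 1) {
  D <- if (is.list(trace)) trace$D else as.numeric(trace)
  if (is.list(trace) && !is.null(trace$bin)) bin <- trace$bin
  n <- length(D)
  stopifnot(n >= 2)
  if (is.null(max_lag)) max_lag <- floor(n / 4) * bin
  nl <- min(floor(max_lag / bin), n - 1L)
  ac <- stats::acf(D, lag.max = nl, type = "covariance", plot = FALSE,
                   demean = TRUE)
  data.frame(lag = (0:nl) * bin, C = as.numeric(ac$acf))
}

#' First non-zero-lag autocorrelation peak
#'
#' Lag of the first local maximum at positive lag with `C > 0`: an
#' oscillation recurs with positive correlation at its period, so local
#' maxima inside negative troughs (noise wiggles) are not peaks.
#'
#' @param ac Data frame from [pop_autocorr()].
#' @return Lag (ms) of the first oscillation peak, or `NA` if none exists.
#' @export
autocorr_first_peak <- function(ac) {
  C <- ac$C
  n <- length(C)
  if (n < 3) return(NA_real_)
  loc <- which(C[2:(n - 1)] > C[1:(n - 2)] & C[2:(n - 1)] >= C[3:n] &
                 C[2:(n - 1)] > 0) + 1L
  loc <- loc[loc > 1L]
  if (!length(loc)) return(NA_real_)
  ac$lag[loc[1L]]
}

# analytic signal via FFT (one-sided spectrum doubling)
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Kuramoto order parameter from Hilbert-transform phases
#'
#' Centers each signal, extracts instantaneous phases from the analytic
#' signal over the analysis window, and computes the instantaneous order
#' parameter \eqn{r(t) = |\frac1N \sum_j e^{i\psi_j(t)}|}; constant signals
#' have no defined phase and are excluded with a warning.
#'
#' @param signals Neurons x time matrix (rates or membrane potentials on a
#'   regular grid).
#' @param window Length-2 analysis window in sample indices (inclusive), or
#'   `NULL` for the full record.
#' @return Object of class `kuramoto_result` with `r_t` (instantaneous),
#'   `r_mean` (time-averaged), `psi` (phases) and the window used.
#' @export
kuramoto <- function(signals, window = NULL) {
  signals <- rbind(signals)
  if (nrow(signals) < 2L)
    stop("kuramoto: need at least two signals", call. = FALSE)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] >= 1,
              window[2] <= ncol(signals), window[1] < window[2])
    signals <- signals[, window[1]:window[2], drop = FALSE]
  }
  keep <- apply(signals, 1L, function(x) stats::sd(x) > 0)
  if (!all(keep)) {
    warning("kuramoto: excluding ", sum(!keep), " constant signal(s)")
    signals <- signals[keep, , drop = FALSE]
  }
  if (nrow(signals) < 2L)
    stop("kuramoto: fewer than two non-constant signals", call. = FALSE)
  ph <- t(apply(signals, 1L, function(x) Arg(.analytic_signal(x - mean(x)))))
  z <- colMeans(exp(1i * ph))
  structure(list(r_t = Mod(z), r_mean = mean(Mod(z)), psi = ph,
                 n = nrow(signals)), class = "kuramoto_result")
}

#' Circular readout-error statistics
#'
#' Wrap-aware error statistics of angle estimates against the true
#' direction: errors are computed on the circle, then summarized by the
#' circular mean error, the mean absolute error, and the circular standard
#' deviation (resultant-vector definition).
#'
#' @param angle_estimates Vector (or matrix, trials x windows) of estimated
#'   angles (rad).
#' @param theta_true True direction (rad), scalar or matching shape.
#' @return If `angle_estimates` is a vector: list with `mean_error`,
#'   `mean_abs_error`, `circ_sd`. If a matrix: data frame with one row per
#'   column.
#' @export
readout_error_stats <- function(angle_estimates, theta_true) {
  stat1 <- function(est, th) {
    d <- atan2(sin(est - th), cos(est - th))
    Rbar <- Mod(mean(exp(1i * d)))
    list(mean_error = atan2(mean(sin(d)), mean(cos(d))),
         mean_abs_error = mean(abs(d)),
         circ_sd = sqrt(pmax(-2 * log(pmax(Rbar, 1e-12)), 0)))
  }
  if (is.matrix(angle_estimates)) {
    out <- do.call(rbind, lapply(seq_len(ncol(angle_estimates)), function(j) {
      s <- stat1(angle_estimates[, j], theta_true)
      data.frame(window = j, mean_error = s$mean_error,
                 mean_abs_error = s$mean_abs_error, circ_sd = s$circ_sd)
    }))
    return(out)
  }
  stat1(angle_estimates, theta_true)
}

#' Column-wise correlation of a weight matrix
#'
#' Pearson correlation between the columns of `W` (the afferent weight
#' pattern of each input neuron); columns with zero variance give `NA`
#' entries.
#'
#' @param W Weight matrix with >= 2 rows.
#' @return Correlation matrix with unit diagonal (NA where undefined).
#' @export
weight_correlation <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) < 2L)
    stop("weight_correlation: need >= 2 rows", call. = FALSE)
  sds <- apply(W, 2L, stats::sd)
  R <- suppressWarnings(stats::cor(W))
  R[, sds == 0] <- NA_real_
  R[sds == 0, ] <- NA_real_
  diag(R)[sds > 0] <- 1
  R
}

# pairwise-distance sums for the energy statistic
.edist_stat <- function(X, Y) {
  nx <- nrow(X); ny <- nrow(Y)
  dxy <- sqrt(outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * X %*% t(Y))
  dxx <- stats::dist(X); dyy <- stats::dist(Y)
  2 * mean(dxy) - 2 * sum(dxx) / (nx * nx) - 2 * sum(dyy) / (ny * ny)
}

#' Energy-distance test of readout Gaussianity
#'
#' Two-sample energy-distance test comparing readout samples with a Gaussian
#' sample matched in mean and covariance; the p-value comes from a
#' permutation null over the pooled samples.
#'
#' @param readout_samples n x d matrix of readout draws (n >= 100).
#' @param n_perm Number of permutations.
#' @param alpha Test level for the returned decision.
#' @param seed Optional seed for the matched-Gaussian draw and permutations.
#' @return List with `statistic`, `p_value`, `reject` (at `alpha`).
#' @export
gaussianity_check <- function(readout_samples, n_perm = 200, alpha = 0.05,
                              seed = NULL) {
  X <- as.matrix(readout_samples)
  if (nrow(X) < 100L)
    stop("gaussianity_check: need at least 100 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- colMeans(X)
  S <- stats::cov(X)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <
      1e-12 * max(diag(S)))
    S <- S + diag(1e-10 * max(diag(S)) + 1e-300, ncol(X))
  Y <- MASS::mvrnorm(nrow(X), mu, S)
  stat <- .edist_stat(X, Y)
  pooled <- rbind(X, Y)
  n <- nrow(X)
  perm <- replicate(n_perm, {
    idx <- sample.int(2 * n, n)
    .edist_stat(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE])
  })
  p <- (1 + sum(perm >= stat)) / (n_perm + 1)
  list(statistic = stat, p_value = p, reject = p < alpha)
}
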