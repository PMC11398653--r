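# Spiking network reconstruction: the trained moment-network weights and
# external currents are reused verbatim as the synaptic weights (mV per
# spike) and constant external drive of a feedforward LIF network. Sensory
# input is either inhomogeneous Poisson spiking from the deterministic rate
# traces or a correlated Gaussian current matched to given moments. The
# numerical core lives in compiled code; R-level helpers exist for single
# steps and spike generation so the scheme itself is testable in isolation.

#' Single Euler step of a LIF population
#'
#' Advances membrane potentials by one explicit Euler step
#' `V <- V + (-L V) dt + drive`, emitting spikes on threshold crossings and
#' enforcing reset and refractory clamping (bookkeeping exact to `dt`
#' resolution).
#'
#' @param state List with `V` (mV) and `ref` (remaining refractory steps).
#' @param input_current Total drive for this step: either a charge increment
#'   (mV) already including `dt`, or current (mV/ms) via `current_scale = dt`.
#' @param dt Step (ms).
#' @param params [lif_params()].
#' @param current_scale Multiplier applied to `input_current` (use `dt` when
#'   passing a current rather than a charge).
#' @return List with updated `state` and logical `spiked`.
#' @export
step_lif <- function(state, input_current, dt, params = lif_params(),
                     current_scale = 1) {
  n <- length(state$V)
  spiked <- logical(n)
  refr <- state$ref > 0
  state$ref[refr] <- state$ref[refr] - 1L
  state$V[refr] <- params$V_res
  act <- !refr
  v <- state$V[act] - params$L * state$V[act] * dt +
    input_current[act] * current_scale
  fire <- v >= params$V_th
  v[fire] <- params$V_res
  state$V[act] <- v
  spiked[act] <- fire
  state$ref[act][fire] <- as.integer(round(params$T_ref / dt))
  list(state = state, spiked = spiked)
}

#' Inhomogeneous Poisson spike trains by per-bin Bernoulli thinning
#'
#' Generates spikes from per-step rates with `P(spike) = rate * dt` per bin
#' (error `O(rate * dt)`).
#'
#' @param rate_traces Neurons x steps matrix of rates (sp/ms), or a vector
#'   for a single neuron.
#' @param dt Step (ms); `max(rate) * dt` must not exceed 1.
#' @return Logical matrix of spikes, neurons x steps.
#' @export
poisson_spikes <- function(rate_traces, dt) {
  rate_traces <- rbind(rate_traces)
  stopifnot(all(rate_traces >= 0), dt > 0)
  if (max(rate_traces) * dt > 1)
    stop("poisson_spikes: rate * dt exceeds 1; reduce dt", call. = FALSE)
  p <- rate_traces * dt
  matrix(stats::runif(length(p)) < p, nrow(p), ncol(p))
}

#' Reconstruct a spiking network from a trained moment network
#'
#' @param trained A `trained_mnn`/`trained_classifier` or an [mnn_network()]
#'   whose normalization has been absorbed ([absorb_batchnorm()]).
#' @return Object of class `snn` holding the layer weights, external
#'   currents, readout, and LIF parameters.
#' @export
reconstruct_snn <- function(trained) {
  net <- if (inherits(trained, "trained_mnn")) trained$network
         else if (inherits(trained, "trained_classifier")) trained$model
         else trained
  stopifnot(inherits(net, "mnn_network"))
  if (any(!vapply(net$layers, function(l) is.null(l$bn), logical(1))))
    stop("reconstruct_snn: absorb the normalization first ",
         "(absorb_batchnorm)", call. = FALSE)
  structure(list(
    Ws = lapply(net$layers, `[[`, "W"),
    mu_exts = lapply(net$layers, `[[`, "mu_ext"),
    W_out = net$W_out, b_out = net$b_out,
    params = net$params,
    input_size = net$input_size,
    hidden_sizes = net$hidden_sizes
  ), class = "snn")
}

#' @export
print.snn <- function(x, ...) {
  cat(sprintf("spiking network: %d -> %s (LIF), linear readout %d\n",
              x$input_size, paste(x$hidden_sizes, collapse = " -> "),
              nrow(x$W_out)))
  invisible(x)
}

.sim_config <- function(dt = 0.1, duration = 1256, trials = 10, seed = 1,
                        bin = 1) {
  stopifnot(dt > 0, duration > 0, trials >= 1, bin >= dt)
  list(dt = dt, duration = duration, trials = trials, seed = seed, bin = bin)
}

#' Simulation settings for the spiking network
#'
#' @param dt Time increment (ms), default 0.1.
#' @param duration Simulated time per trial (ms), default 1256.
#' @param trials Number of independent trials.
#' @param seed Integer seed.
#' @param bin Width (ms) of the spike-count bins in the returned records.
#' @return A plain list of validated settings.
#' @export
sim_config <- function(dt = 0.1, duration = 1256, trials = 10, seed = 1,
                       bin = 1) {
  .sim_config(dt, duration, trials, seed, bin)
}

# shared post-processing of the compiled simulator output
.collect_trials <- function(raw, snn, cfg) {
  lapply(raw, function(tr) {
    names(tr$counts) <- paste0("layer", seq_along(tr$counts))
    tr
  })
}

#' Simulate the spiking network under Poisson sensory drive
#'
#' Runs `cfg$trials` independent trials of the reconstructed network with
#' sensory spikes drawn as inhomogeneous Poisson processes from the
#' stimulus's deterministic rate traces. Hidden membrane potentials of each
#' layer are recorded at the bin resolution; initial potentials are uniform
#' on `[V_res, V_th)`.
#'
#' @param snn A [reconstruct_snn()] network.
#' @param stimulus An `encoded_stimulus` (from [encode_grating()]) providing
#'   `rate_traces`.
#' @param cfg A [sim_config()].
#' @return List of trials; each has `counts` (list per layer of neurons x
#'   bins spike counts), `input_pop` (total sensory spikes per bin) and
#'   `vtraces` (list per layer of membrane potentials sampled at bin ends).
#' @export
run_snn_poisson <- function(snn, stimulus, cfg = sim_config()) {
  stopifnot(inherits(snn, "snn"))
  nsteps <- round(cfg$duration / cfg$dt)
  t_grid <- (seq_len(nsteps) - 1L) * cfg$dt
  rates <- stimulus$rate_traces(t_grid)
  stopifnot(nrow(rates) == snn$input_size)
  if (max(rates) * cfg$dt > 1)
    stop("rate * dt exceeds 1", call. = FALSE)
  set.seed(cfg$seed)
  raw <- cpp_snn_sim(snn$Ws, snn$mu_exts, 0L, rates, numeric(0),
                     matrix(0, 0, 0), nsteps, cfg$dt,
                     as.integer(round(cfg$bin / cfg$dt)), cfg$trials,
                     snn$params$L, snn$params$V_th, snn$params$V_res,
                     snn$params$T_ref, TRUE, TRUE)
  .collect_trials(raw, snn, cfg)
}

#' Simulate the spiking network under correlated Gaussian current drive
#'
#' Injects current increments with mean `mu * dt` and covariance
#' `Sigma * dt` per step into the first layer, so spike-count statistics over
#' a window match the given per-unit-time moments.
#'
#' @param snn A [reconstruct_snn()] network.
#' @param mu,Sigma Drive moments on the per-unit-time scale (mV/ms and
#'   mV^2/ms). `Sigma` must be PSD.
#' @param cfg A [sim_config()].
#' @return As [run_snn_poisson()] (without a meaningful `input_pop`).
#' @export
run_snn_gaussian <- function(snn, mu, Sigma, cfg = sim_config()) {
  stopifnot(inherits(snn, "snn"))
  Sigma <- as.matrix(Sigma)
  .assert_psd(Sigma)
  n1 <- length(snn$mu_exts[[1]])
  stopifnot(length(mu) == n1, nrow(Sigma) == n1)
  # the Gaussian drive replaces the synaptic input of layer 1; absorb W mu
  ch <- tryCatch(t(chol(Sigma + diag(1e-12, n1))),
                 error = function(e) stop("run_snn_gaussian: covariance ",
                                          "factorization failed",
                                          call. = FALSE))
  nsteps <- round(cfg$duration / cfg$dt)
  set.seed(cfg$seed)
  raw <- cpp_snn_sim(snn$Ws, snn$mu_exts, 1L, matrix(0, 0, 0), mu, ch,
                     nsteps, cfg$dt, as.integer(round(cfg$bin / cfg$dt)),
                     cfg$trials, snn$params$L, snn$params$V_th,
                     snn$params$V_res, snn$params$T_ref, TRUE, TRUE)
  .collect_trials(raw, snn, cfg)
}

#' Time-resolved linear readout of spike records
#'
#' Applies the trained readout to cumulative spike counts,
#' `y(T) = W_out n(T) / T + b`, for a grid of readout window lengths, and
#' returns per-trial readouts and angle estimates.
#'
#' @param snn The [reconstruct_snn()] network.
#' @param trials Output of [run_snn_poisson()] / [run_snn_gaussian()].
#' @param windows Readout window lengths (ms), multiples of the record bin.
#' @param bin Record bin width (ms).
#' @return List with `y` (trials x windows x readout-dim array) and
#'   `theta_hat` (trials x windows).
#' @export
snn_readout <- function(snn, trials, windows, bin = 1) {
  last <- length(snn$Ws)
  K <- nrow(snn$W_out)
  nt <- length(trials)
  y <- array(NA_real_, c(nt, length(windows), K))
  for (tr in seq_len(nt)) {
    counts <- trials[[tr]]$counts[[last]]
    cum <- t(apply(counts, 1L, cumsum))
    for (wi in seq_along(windows)) {
      nb <- round(windows[wi] / bin)
      stopifnot(nb >= 1, nb <= ncol(cum))
      yv <- drop(snn$W_out %*% (cum[, nb] / windows[wi]))
      if (!is.null(snn$b_out)) yv <- yv + snn$b_out
      y[tr, wi, ] <- yv
    }
  }
  out <- list(y = y, windows = windows)
  if (K == 2L) out$theta_hat <- atan2(y[, , 2], y[, , 1])
  out
}

#' Direction-task trials of the reconstructed spiking network
#'
#' Convenience wrapper: encodes a grating, simulates Poisson-driven trials,
#' and computes the time-resolved readout.
#'
#' @param snn A [reconstruct_snn()] direction network.
#' @param stim A [grating_stimulus()].
#' @param array The detector array used in training.
#' @param cfg A [sim_config()].
#' @param windows Readout windows (ms).
#' @return List with the raw `trials`, the readout (`y`, `theta_hat`), and
#'   the stimulus.
#' @export
run_direction_trials <- function(snn, stim, array, cfg = sim_config(),
                                 windows = c(10, 20, 50, 100, 200, 400,
                                             800, 1200)) {
  enc <- encode_grating(stim, array)
  trials <- run_snn_poisson(snn, enc, cfg)
  windows <- windows[windows <= cfg$duration]
  ro <- snn_readout(snn, trials, windows, cfg$bin)
  list(trials = trials, readout = ro, stim = stim)
}
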