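# Lazily trained direction model shared across test files (training and
# spiking simulations are the expensive parts of the suite, so they run once
# and are memoized for the session).

.test_cache <- new.env(parent = emptyenv())

test_array <- function() {
  if (is.null(.test_cache$array))
    .test_cache$array <- make_hexagonal_grid(61)
  .test_cache$array
}

# reduced-scale trained direction model (61 sites, 48 hidden)
trained_model <- function() {
  if (is.null(.test_cache$trained)) {
    arr <- test_array()
    net <- mnn_network(2L * arr$n_sites, 48, 2, seed = 5)
    .test_cache$trained <- train_direction_task(
      net, arr, epochs = 10, samples_per_epoch = 800, batch_size = 25,
      lr = 1e-3, val_size = 150, seed = 42)
  }
  .test_cache$trained
}

# direction-averaged, trial-averaged normalized population count of the
# reconstructed spiking network under the c = 0.8 grating (onset discarded)
entrainment_traces <- function(n_dirs = 10, n_trials = 15) {
  key <- sprintf("entrain_%d_%d", n_dirs, n_trials)
  if (is.null(.test_cache[[key]])) {
    tr <- trained_model()
    snn <- reconstruct_snn(tr)
    dirs <- seq(-pi, pi, length.out = n_dirs + 1L)[-(n_dirs + 1L)]
    P <- 0; C <- 0
    for (i in seq_along(dirs)) {
      cfg <- sim_config(dt = 0.1, duration = 1256, trials = n_trials,
                        seed = 900 + i)
      out <- run_direction_trials(snn, grating_stimulus(0.8, dirs[i]),
                                  tr$array, cfg, windows = 100)
      Dbar <- 0
      for (t_i in out$trials)
        Dbar <- Dbar +
          normalize_pop_count(t_i$counts$layer1[, 201:1256])$D / n_trials
      P <- P + pop_psd(Dbar, bin = 1)$power / n_dirs
      C <- C + pop_autocorr(Dbar, max_lag = 30, bin = 1)$C / n_dirs
    }
    freq <- pop_psd(numeric(1056), bin = 1)$freq
    .test_cache[[key]] <- list(psd = data.frame(freq = freq, power = P),
                               ac = data.frame(lag = 0:30, C = C))
  }
  .test_cache[[key]]
}
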