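test_that("step_lif: leak decay, reset, refractory bookkeeping", {
  p <- lif_params()
  st <- list(V = 10, ref = 0L)
  for (i in 1:100) st <- step_lif(st, 0, 0.1, p)$state
  expect_equal(st$V, 10 * exp(-p$L * 0.1 * 100)^1, tolerance = 0.01)
  expect_gt(st$V, 0)
  # constant superthreshold drive: ISI = T_ref + (1/L) log(mu/(mu - Vth L))
  dt <- 0.1
  st <- list(V = 0, ref = 0L)
  spikes <- integer(0)
  for (i in 1:2000) {
    r <- step_lif(st, 2, dt, p, current_scale = dt)
    st <- r$state
    if (r$spiked) spikes <- c(spikes, i)
  }
  isi <- diff(spikes) * dt
  expect_lt(abs(mean(isi) - (5 + 20 * log(2))), dt + 1e-9)
  # reset contract: V = V_res right after a spike, silent during T_ref
  i_spk <- spikes[1]
  st2 <- list(V = 0, ref = 0L)
  for (i in 1:i_spk) {
    r <- step_lif(st2, 2, dt, p, current_scale = dt)
    st2 <- r$state
  }
  expect_equal(st2$V, p$V_res)
  for (i in seq_len(round(p$T_ref / dt))) {
    r <- step_lif(st2, 2, dt, p, current_scale = dt)
    st2 <- r$state
    expect_false(any(r$spiked))
  }
})

test_that("poisson_spikes: silence, unbiased counts, rate cap", {
  expect_equal(sum(poisson_spikes(matrix(0, 2, 100), 0.1)), 0)
  set.seed(21)
  sp <- poisson_spikes(matrix(1, 1, 1e5), 0.1)  # 1 sp/ms for 1e4 ms
  expect_lt(abs(sum(sp) - 1e4), 3 * sqrt(1e4))
  expect_error(poisson_spikes(matrix(20, 1, 10), 0.1), "exceeds 1")
})

test_that("reconstruction requires absorbed normalization and keeps weights", {
  net <- mnn_network(4, 3, 2, seed = 1)
  expect_error(reconstruct_snn(net), "absorb")
  net$layers[[1]]$bn <- NULL
  snn <- reconstruct_snn(net)
  expect_identical(snn$Ws[[1]], net$layers[[1]]$W)
  expect_identical(snn$W_out, net$W_out)
})

test_that("zero-weight network with subthreshold drive stays silent", {
  net <- mnn_network(2, 3, 2, seed = 1)
  net$layers[[1]]$bn <- NULL
  net$layers[[1]]$W[] <- 0
  net$layers[[1]]$mu_ext <- rep(0.5, 3)   # below V_th * L = 1
  snn <- reconstruct_snn(net)
  enc <- list(mu = c(1, 1), Sigma = diag(2),
              rate_traces = function(tg) matrix(1, 2, length(tg)))
  out <- run_snn_poisson(snn, enc, sim_config(duration = 500, trials = 2,
                                              seed = 3))
  expect_equal(sum(out[[1]]$counts$layer1), 0)
})

test_that("Gaussian current drive reproduces the analytic operating point", {
  # single neuron at (mu, sigma) = (1.5, 1): long-run rate and count variance
  # match the moment activation within Monte-Carlo error
  net <- mnn_network(1, 1, 1, seed = 1)
  net$layers[[1]]$bn <- NULL
  net$layers[[1]]$W <- matrix(0, 1, 1)
  net$layers[[1]]$mu_ext <- 0
  snn <- reconstruct_snn(net)
  cfg <- sim_config(dt = 0.02, duration = 2e5, trials = 1, seed = 5,
                    bin = 2000)
  out <- run_snn_gaussian(snn, mu = 1.5, Sigma = matrix(1), cfg)
  cnt <- as.numeric(out[[1]]$counts$layer1)
  emp_mu <- mean(cnt) / 2000
  se_mu <- sd(cnt) / 2000 / sqrt(length(cnt))
  expect_lt(abs(emp_mu - phi_mu(1.5, 1)), 3 * se_mu + 0.002 * phi_mu(1.5, 1))
  emp_var <- var(cnt) / 2000
  se_var <- emp_var * sqrt(2 / (length(cnt) - 1))
  expect_lt(abs(emp_var - phi_sigma(1.5, 1)^2), 3 * se_var)
  # refractory bound respected in the record
  expect_true(all(cnt <= 2000 / lif_params()$T_ref))
})

test_that("moment activation predicts spiking statistics of a small network", {
  # three LIF neurons sharing Poisson afferents: empirical rate, count
  # variance and pairwise correlation over long windows agree with the
  # analytic moment mapping (weak-correlation regime)
  p <- lif_params()
  W <- matrix(c(0.45, 0.10, 0.05,
                0.10, 0.50, 0.10,
                0.05, 0.10, 0.45,
                0.15, 0.05, 0.15), 3, 4)
  lam <- c(2, 1.6, 1.9, 2.3)
  mu_ext <- c(0.6, 0.55, 0.6)
  pred <- moment_activate(current_moments(drop(W %*% lam) + mu_ext,
                                          W %*% diag(lam) %*% t(W)))
  nsteps <- 6e6L   # 600 s at 0.1 ms
  rates <- matrix(rep(lam, nsteps), 4)
  set.seed(13)
  raw <- momentcov:::cpp_snn_sim(list(W), list(mu_ext), 0L, rates,
                                 numeric(0), matrix(0, 0, 0), nsteps, 0.1,
                                 20000L, 1L, p$L, p$V_th, p$V_res, p$T_ref,
                                 FALSE, TRUE)
  cnt <- raw[[1]]$counts[[1]]
  win <- 2000
  nw <- ncol(cnt)
  emp_mu <- rowMeans(cnt) / win
  se_mu <- apply(cnt, 1, sd) / win / sqrt(nw)
  expect_true(all(abs(emp_mu - pred$mu) < 3 * se_mu + 0.01 * pred$mu))
  emp_cov <- cov(t(cnt)) / win
  se_var <- diag(emp_cov) * sqrt(2 / (nw - 1))
  expect_true(all(abs(diag(emp_cov) - pred$sigma^2) < 3 * se_var))
  emp_rho <- cor(t(cnt))
  se_rho <- (1 - emp_rho^2) / sqrt(nw - 3)
  off <- upper.tri(emp_rho)
  expect_true(all(abs(emp_rho[off] - pred$rho[off]) <
                    3 * se_rho[off] + 0.05))
})

test_that("Euler scheme is converged at the default step", {
  set.seed(3)
  r1 <- lif_mc_oracle(2, 1, T_ms = 2e5, dt = 0.01)
  r2 <- lif_mc_oracle(2, 1, T_ms = 2e5, dt = 0.005)
  expect_lt(abs(r1$mu - r2$mu) / r2$mu, 0.01 + 3 * r1$se_mu / r2$mu)
})

test_that("simulations are reproducible under a fixed seed", {
  tr <- trained_model()
  snn <- reconstruct_snn(tr)
  enc <- encode_grating(grating_stimulus(0.8, 0.3), tr$array)
  cfg <- sim_config(duration = 100, trials = 2, seed = 11)
  o1 <- run_snn_poisson(snn, enc, cfg)
  o2 <- run_snn_poisson(snn, enc, cfg)
  expect_identical(o1[[1]]$counts, o2[[1]]$counts)
  expect_identical(o1[[2]]$vtraces, o2[[2]]$vtraces)
})

test_that("readout variance shrinks roughly as 1/window on stationary activity", {
  tr <- trained_model()
  snn <- reconstruct_snn(tr)
  out <- run_direction_trials(snn, grating_stimulus(0.8, 0.3), tr$array,
                              sim_config(duration = 1256, trials = 24,
                                         seed = 19),
                              windows = c(100, 400, 1200))
  v <- apply(out$readout$y, 2, function(m) mean(apply(m, 2, var)))
  # variance ratio between 100 ms and 1200 ms windows ~ 12, allow wide band
  expect_gt(v[1] / v[3], 4)
  expect_gt(v[1] / v[2], 1.5)
})

test_that("hidden rates respect the refractory bound in direction trials", {
  tr <- trained_model()
  snn <- reconstruct_snn(tr)
  out <- run_direction_trials(snn, grating_stimulus(0.8, 1.2), tr$array,
                              sim_config(duration = 400, trials = 3,
                                         seed = 23), windows = 400)
  for (t_i in out$trials) {
    rates_hz <- rowSums(t_i$counts$layer1) / 400 * 1000
    expect_true(all(rates_hz <= 200))
  }
})
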