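test_that("synaptic summation implements the linear moment map", {
  sm <- spike_moments(c(1, 2), c(0.5, 0.8),
                      matrix(c(1, 0.4, 0.4, 1), 2))
  # zero weights pass the external moments through
  cm0 <- synaptic_summation(matrix(0, 3, 2), sm, mu_ext = c(1, 2, 3))
  expect_equal(cm0$mu, c(1, 2, 3))
  expect_equal(cm0$Sigma, matrix(0, 3, 3))
  # scalar case
  cm1 <- synaptic_summation(matrix(2, 1, 1),
                            list(mu = 3, Sigma = matrix(1.5)), mu_ext = 0.5)
  expect_equal(cm1$mu, 6.5)
  expect_equal(cm1$Sigma[1, 1], 4 * 1.5)
  expect_error(synaptic_summation(matrix(0, 3, 5), sm), "mismatch")
})

test_that("W Sigma W' matches the covariance of linearly mapped samples", {
  set.seed(11)
  W <- matrix(rnorm(24), 4, 6)
  A <- matrix(rnorm(36), 6)
  S <- crossprod(A) / 6
  X <- MASS::mvrnorm(2e4, rep(0, 6), S)
  emp <- cov(X %*% t(W))
  ana <- synaptic_summation(W, list(mu = rep(0, 6), Sigma = S))$Sigma
  expect_lt(max(abs(emp - ana)), 4 * max(diag(ana)) * sqrt(2 / 2e4) * 3)
})

test_that("moment batch-normalization: congruence and statistics", {
  set.seed(2)
  H <- 4
  state <- list(gamma = rep(1, H), beta = rep(0, H),
                running_mean = numeric(H), running_var = rep(1, H),
                eps = 1e-5, momentum = 0.1, initialized = FALSE)
  batch <- lapply(1:6, function(i) {
    A <- matrix(rnorm(H * H), H)
    current_moments(rnorm(H, 2), crossprod(A) / H)
  })
  out <- moment_batchnorm(batch, state, mode = "train")
  m2 <- sapply(out$output, `[[`, "mu")
  expect_equal(rowMeans(m2), rep(0, H), tolerance = 1e-10)
  expect_true(out$state$initialized)
  # covariance transformed as a diagonal congruence: scaling feature d
  # scales row/column d of the covariance by the same factor
  d1 <- out$output[[1]]$Sigma / batch[[1]]$Sigma
  dvec <- sqrt(diag(d1))
  expect_equal(d1, tcrossprod(dvec), tolerance = 1e-8)
  expect_error(moment_batchnorm(batch[[1]], state, mode = "eval"),
               "running statistics")
  expect_error(moment_batchnorm(batch[1], state, mode = "train"), "batch")
})

test_that("normalization absorbs exactly into the summation layer", {
  set.seed(4)
  net <- mnn_network(6, c(5, 4), 2, seed = 8)
  batch <- lapply(1:8, function(i) {
    A <- matrix(rnorm(36), 6)
    list(mu = runif(6, 0.5, 1.5), Sigma = crossprod(A) / 6 + diag(0.3, 6))
  })
  MU <- do.call(rbind, lapply(batch, `[[`, "mu"))
  fw <- momentcov:::.mnn_fwd(net, MU, lapply(batch, `[[`, "Sigma"),
                             training = TRUE)
  for (l in 1:2) net$layers[[l]]$bn <- fw$caches[[l]]$bnf$state
  flat <- absorb_batchnorm(net)
  expect_true(all(vapply(flat$layers, function(l) is.null(l$bn), logical(1))))
  worst <- 0
  for (b in batch) {
    o1 <- mnn_forward(net, b)
    o2 <- mnn_forward(flat, b)
    worst <- max(worst,
                 max(abs(o1$mu_hat - o2$mu_hat)) / max(abs(o1$mu_hat)),
                 max(abs(o1$Sigma_hat - o2$Sigma_hat)) /
                   max(max(abs(o1$Sigma_hat)), 1e-12))
  }
  expect_lt(worst, 1e-6)
  # double absorption is a no-op
  expect_identical(absorb_batchnorm(flat), flat)
  # absorbing an untrained network is an error
  expect_error(absorb_batchnorm(mnn_network(6, 5, 2, seed = 1)),
               "statistics")
})

test_that("forward pass: determinism, stimulus independence at W = 0, shapes", {
  arr <- make_hexagonal_grid(19)
  net <- mnn_network(2L * arr$n_sites, 12, 2, seed = 3)
  # initialize running stats
  ds <- direction_dataset(4, arr, seed = 1)
  MU <- do.call(rbind, lapply(ds$stimuli, `[[`, "mu"))
  fw <- momentcov:::.mnn_fwd(net, MU, lapply(ds$stimuli, `[[`, "Sigma"),
                             training = TRUE)
  net$layers[[1]]$bn <- fw$caches[[1]]$bnf$state
  e1 <- encode_grating(grating_stimulus(0.7, 0.5), arr)
  o1 <- mnn_forward(net, e1)
  expect_identical(o1, mnn_forward(net, e1))   # bitwise-stable
  expect_length(o1$mu_hat, 2L)
  expect_equal(dim(o1$Sigma_hat), c(2L, 2L))
  expect_equal(o1$theta_hat, atan2(o1$mu_hat[2], o1$mu_hat[1]))
  # zero input weights: hidden moments independent of the stimulus
  net0 <- net
  net0$layers[[1]]$W[] <- 0
  h1 <- mnn_forward(net0, e1, return_hidden = TRUE)$hidden[[1]]
  h2 <- mnn_forward(net0, encode_grating(grating_stimulus(0.2, -2), arr),
                    return_hidden = TRUE)$hidden[[1]]
  expect_equal(h1$mu, h2$mu)
  expect_equal(h1$Sigma, h2$Sigma)
})

test_that("only the nonlinear moment coupling extracts direction", {
  # the input mean is direction-independent, so any linear map of the means
  # is too; the rate output of the moment activation is not
  arr <- make_hexagonal_grid(37)
  net <- mnn_network(2L * arr$n_sites, 16, 2, seed = 6)
  thetas <- c(-2, -0.5, 1, 2.5)
  encs <- lapply(thetas, function(th)
    encode_grating(grating_stimulus(0.8, th), arr))
  W <- net$layers[[1]]$W
  lin_means <- sapply(encs, function(e) drop(W %*% e$mu))
  expect_lt(max(apply(lin_means, 1, sd)), 1e-12)
  act_means <- sapply(encs, function(e) {
    cm <- synaptic_summation(W, e, mu_ext = 1)
    moment_activate(cm)$mu
  })
  expect_gt(max(apply(act_means, 1, sd)), 1e-5)
})

test_that("full-size direction architecture is accepted", {
  arr <- make_hexagonal_grid(527)
  net <- mnn_network(2L * arr$n_sites, 2L * arr$n_sites, 2, seed = 1)
  # bypass normalization (untrained) for a pure shape/feasibility check
  net$layers[[1]]$bn <- NULL
  o <- mnn_forward(net, encode_grating(grating_stimulus(0.5, 0.3), arr))
  expect_length(o$mu_hat, 2L)
  expect_equal(dim(o$Sigma_hat), c(2L, 2L))
  expect_true(all(is.finite(o$mu_hat)))
})

test_that("tuning curves: flat at zero contrast, non-negative Fano, contrast growth", {
  tr <- trained_model()
  tc0 <- tuning_curves(tr$network, tr$array,
                       directions = seq(-pi, pi, length.out = 13)[-13],
                       contrasts = c(0, 0.75))
  # zero contrast: no direction signal in the input moments
  expect_lt(max(apply(tc0$rate[, 1, ], 2, sd)), 1e-12)
  expect_true(all(tc0$fano >= 0))
  # tuning height grows with contrast for most neurons
  height <- apply(tc0$rate, 2:3, max)
  expect_gt(mean(height[2, ] > height[1, ]), 0.8)
  expect_true(all(tc0$preferred >= -pi & tc0$preferred < pi))
})
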