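test_that("angular loss: exact limits and Monte-Carlo consistency", {
  expect_equal(angular_loss(c(2, 0), diag(0, 2), 0, n_samples = 8), 0,
               tolerance = 1e-3)
  expect_equal(angular_loss(c(-2, 0), diag(0, 2), 0, n_samples = 8), pi,
               tolerance = 1e-3)
  # right angle, zero covariance
  expect_equal(angular_loss(c(0, 1), diag(0, 2), 0, n_samples = 8), pi / 2,
               tolerance = 1e-2)
})

test_that("MC angular loss is an unbiased estimator of the integral", {
  th <- 0.4
  mu <- c(cos(th), sin(th))
  S <- 0.1 * diag(2)
  truth <- angular_loss_quad(mu, S, th)
  set.seed(31)
  est <- replicate(100, angular_loss(mu, S, th, n_samples = 32))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se)
  # a second, anisotropic case
  S2 <- matrix(c(0.3, 0.1, 0.1, 0.15), 2)
  truth2 <- angular_loss_quad(mu, S2, th)
  est2 <- replicate(100, angular_loss(mu, S2, th, n_samples = 32))
  expect_lt(abs(mean(est2) - truth2), 3 * sd(est2) / sqrt(100))
})

test_that("loss gradients match finite differences", {
  set.seed(5)
  z <- matrix(rnorm(2 * 64), 64, 2)
  mu <- c(0.4, -0.2)
  S <- matrix(c(0.2, 0.05, 0.05, 0.3), 2)
  g <- momentcov:::.angular_loss_1(mu, S, 1.1, z, 1e-6)
  f <- function(m, Sm) momentcov:::.angular_loss_1(m, Sm, 1.1, z, 1e-6,
                                                   grad = FALSE)$loss
  eps <- 1e-6
  for (i in 1:2) {
    dm <- numeric(2); dm[i] <- eps
    fd <- (f(mu + dm, S) - f(mu - dm, S)) / (2 * eps)
    expect_lt(abs(g$dmu[i] - fd) / max(abs(fd), 1e-8), 1e-4)
  }
  for (idx in list(c(1, 1), c(2, 2))) {
    dS <- matrix(0, 2, 2); dS[idx[1], idx[2]] <- eps
    fd <- (f(mu, S + dS) - f(mu, S - dS)) / (2 * eps)
    expect_lt(abs(g$dSig[idx[1], idx[2]] - fd) / max(abs(fd), 1e-8), 1e-4)
  }
  # symmetric off-diagonal perturbation
  dS <- matrix(c(0, eps, eps, 0), 2)
  fd <- (f(mu, S + dS) - f(mu, S - dS)) / (2 * eps)
  expect_lt(abs(2 * g$dSig[1, 2] - fd) / max(abs(fd), 1e-8), 1e-4)
})

test_that("network gradients match finite differences through the whole model", {
  set.seed(7)
  B <- 3; nin <- 4
  net <- mnn_network(nin, 3, 2, seed = 11)
  MU <- matrix(runif(B * nin, 0.5, 1.5), B, nin)
  Slist <- lapply(1:B, function(e) {
    A <- matrix(rnorm(nin * nin), nin)
    crossprod(A) / nin + diag(0.5, nin)
  })
  theta <- c(-1, 0.3, 2)
  z <- matrix(rnorm(2 * 16), 16, 2)
  lossfun <- function(net) {
    fw <- momentcov:::.mnn_fwd(net, MU, Slist, training = TRUE)
    l <- 0
    for (e in 1:B)
      l <- l + momentcov:::.angular_loss_1(fw$mu_hat[e, ], fw$Sig_hat[[e]],
                                           theta[e], z, 1e-6,
                                           grad = FALSE)$loss / B
    l
  }
  fw <- momentcov:::.mnn_fwd(net, MU, Slist, training = TRUE)
  dmu <- matrix(0, B, 2); dSig <- vector("list", B)
  for (e in 1:B) {
    r <- momentcov:::.angular_loss_1(fw$mu_hat[e, ], fw$Sig_hat[[e]],
                                     theta[e], z, 1e-6)
    dmu[e, ] <- r$dmu / B
    dSig[[e]] <- r$dSig / B
  }
  gr <- momentcov:::.mnn_bwd(net, fw, dmu, dSig)
  check_block <- function(get, set, ana, n_probe = 4) {
    v <- get(net)
    idx <- sample(length(v), min(n_probe, length(v)))
    for (i in idx) {
      eps <- 1e-6
      v1 <- v; v1[i] <- v[i] + eps
      v2 <- v; v2[i] <- v[i] - eps
      fd <- (lossfun(set(net, v1)) - lossfun(set(net, v2))) / (2 * eps)
      expect_lt(abs(ana[i] - fd) / max(abs(fd), 1e-6), 1e-3)
    }
  }
  check_block(function(n) as.vector(n$layers[[1]]$W),
              function(n, v) { n$layers[[1]]$W[] <- v; n },
              as.vector(gr$layers[[1]]$W))
  check_block(function(n) n$layers[[1]]$bn$gamma,
              function(n, v) { n$layers[[1]]$bn$gamma <- v; n },
              gr$layers[[1]]$gamma)
  check_block(function(n) n$layers[[1]]$bn$beta,
              function(n, v) { n$layers[[1]]$bn$beta <- v; n },
              gr$layers[[1]]$beta)
  check_block(function(n) as.vector(n$W_out),
              function(n, v) { n$W_out[] <- v; n },
              as.vector(gr$W_out))
})

test_that("direction training: reproducible, frozen at lr = 0, decreasing trend", {
  arr <- make_hexagonal_grid(19)
  net <- mnn_network(2L * arr$n_sites, 8, 2, seed = 2)
  tr0 <- train_direction_task(net, arr, epochs = 3, samples_per_epoch = 100,
                              batch_size = 20, lr = 0, val_size = 40,
                              seed = 7)
  expect_lt(diff(range(tr0$history$val_loss)), 1e-12)
  tr1 <- train_direction_task(net, arr, epochs = 2, samples_per_epoch = 100,
                              batch_size = 20, lr = 1e-3, val_size = 40,
                              seed = 7)
  tr2 <- train_direction_task(net, arr, epochs = 2, samples_per_epoch = 100,
                              batch_size = 20, lr = 1e-3, val_size = 40,
                              seed = 7)
  expect_identical(tr1$history, tr2$history)
  # the session model: validation loss trend decreases over training
  tr <- trained_model()
  v <- tr$history$val_loss
  k <- min(5, length(v))
  expect_lt(mean(tail(v, k)), mean(head(v, k)))
})

test_that("classifier modes: covariance signal is used, means alone are not", {
  ds <- make_feature_moments(n_per_class = 50, K = 3, C = 12,
                             covariance_separability = 2, L_seq = 600,
                             seed = 10)
  test <- make_feature_moments(n_per_class = 30, K = 3, C = 12,
                               covariance_separability = 2, L_seq = 600,
                               seed = 11, templates = ds$templates)
  accs <- sapply(1:3, function(s) {
    net <- mnn_network(12, 32, 3, seed = 100 + s)
    sapply(c("correlated", "uncorrelated", "mean_only"), function(mode) {
      clf <- train_classifier(net, ds, mode = mode, epochs = 60,
                              batch_size = 25, lr = 3e-3, seed = 200 + s)
      classifier_accuracy(clf, test)
    })
  })
  m <- rowMeans(accs)
  chance <- 1 / 3
  expect_gt(m["correlated"], chance + 0.1)
  expect_gte(m["correlated"], m["uncorrelated"])
  expect_gte(m["uncorrelated"], m["mean_only"] - 0.02)
  expect_lt(m["mean_only"], chance + 0.12)   # ~chance: no usable mean signal
})

test_that("a small moment network learns the two-channel correlation task", {
  task <- make_odor_task(120, rho_magnitude = 0.8, seed = 5)
  om <- odor_task_moments(task)
  net <- mnn_network(2, 8, 2, seed = 9)
  clf <- train_classifier(net, om, mode = "correlated", epochs = 80,
                          batch_size = 20, lr = 3e-3, seed = 4)
  expect_gt(classifier_accuracy(clf, om), 0.75)
})
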