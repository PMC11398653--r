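test_that("dawson g matches closed form and quadrature, stays stable", {
  expect_equal(dawson_g(0), sqrt(pi) / 2, tolerance = 1e-12)
  # asymptotic regime: no overflow, value ~ -1/(2x)
  expect_lt(abs(dawson_g(-40) - g_oracle(-40)) / g_oracle(-40), 1e-9)
  expect_lt(abs(dawson_g(-1e4) - 1 / 2e4) / (1 / 2e4), 1e-6)
  xs <- seq(-5, 5, by = 0.25)
  expect_lt(max(abs(dawson_g(xs) - g_oracle(xs)) / abs(g_oracle(xs))), 1e-8)
  expect_error(dawson_g(NA_real_), "finite")
  expect_error(dawson_g(Inf), "finite")
})

test_that("dawson h matches nested quadrature and is monotone", {
  xs <- c(-10, -6, -3, -1, 0, 0.5, 1, 3, 5, 8, 10)
  ho <- h_oracle(xs)
  expect_lt(max(abs(dawson_h(xs) - ho) / ho), 1e-6)
  # left tail handled by the asymptotic branch
  expect_lt(abs(dawson_h(-30) - 1 / (8 * 30^3)) / (1 / (8 * 30^3)), 1e-2)
  expect_true(all(diff(dawson_h(seq(-12, 9, by = 0.05))) > 0))
  expect_error(dawson_h(NaN), "finite")
})

test_that("integration bounds follow the standardized form", {
  p <- lif_params()
  # sigma_bar * sqrt(L) = 1  =>  I_ub = V_th L - mu, I_lb = V_res L - mu
  s <- 1 / sqrt(p$L)
  b <- integration_bounds(1, s, p)
  expect_equal(b$I_ub, 0)
  expect_equal(b$I_lb, -1)
  b0 <- integration_bounds(0, 2, p)
  expect_gt(b0$I_ub, 0)
  expect_equal(b0$I_lb, 0)
  # width identity for random valid inputs
  set.seed(1)
  mu <- rnorm(20); sg <- runif(20, 0.01, 5)
  bb <- integration_bounds(mu, sg, p)
  expect_equal(bb$I_ub - bb$I_lb,
               (p$V_th - p$V_res) * sqrt(p$L) / sg, tolerance = 1e-12)
  expect_error(integration_bounds(1, 1e-4), "noise floor")
})

test_that("phi_mu: noise-free limit, bounds, monotonicity, continuity", {
  p <- lif_params()
  expect_lt(phi_mu(-10, 0.1), 1e-12)
  expect_equal(phi_mu(2, 0), 1 / (5 + 20 * log(2)), tolerance = 1e-10)
  # refractory bound over a wide grid
  grid <- expand.grid(m = seq(-5, 500, length.out = 60),
                      s = c(0, 0.01, 0.5, 1, 3, 10))
  expect_true(all(phi_mu(grid$m, grid$s) < 1 / p$T_ref))
  # strictly increasing in mean drive at fixed noise
  m <- seq(0.2, 4, by = 0.1)
  expect_true(all(diff(phi_mu(m, 1)) > 0))
  # noise-driven firing: increasing in sigma_bar below threshold drive
  # (above the silent floor, where the rate is identically zero)
  s <- seq(0.6, 3, by = 0.1)
  expect_true(all(diff(phi_mu(0.5, s)) > 0))
  expect_true(all(diff(phi_mu(0.5, seq(0, 0.6, by = 0.1))) >= 0))
  # branch switch at the noise floor is continuous
  expect_lt(abs(phi_mu(2, 1e-3 + 1e-9) - phi_mu(2, 1e-3)), 1e-4)
  expect_lt(abs(phi_mu(0.5, 1e-3 + 1e-9) - phi_mu(0.5, 1e-3)), 1e-4)
})

test_that("phi_sigma limits", {
  expect_equal(phi_sigma(2, 0), 0)
  expect_lt(phi_sigma(2, 1e-3), 1e-3)   # deterministic limit
  expect_equal(phi_sigma(-5, 0.2), 0)   # silent neuron
  expect_true(all(phi_sigma(seq(0, 3, by = 0.5), 1) >= 0))
})

test_that("analytic rate and variance match the Monte-Carlo LIF oracle", {
  set.seed(101)
  for (pt in list(c(1.5, 1), c(1, 0.5), c(2.5, 1.5))) {
    mc <- lif_mc_oracle(pt[1], pt[2], T_ms = 3e5)
    expect_lt(abs(phi_mu(pt[1], pt[2]) - mc$mu), 3 * mc$se_mu)
    expect_lt(abs(phi_sigma(pt[1], pt[2])^2 - mc$var), 3 * mc$se_var)
  }
})

test_that("chi agrees with finite differences and handles silence", {
  p <- lif_params()
  for (pt in list(c(1.5, 1), c(0.8, 0.6), c(3, 2))) {
    m <- pt[1]; s <- pt[2]
    eps <- 1e-5
    fd <- (phi_mu(m + eps, s) - phi_mu(m - eps, s)) / (2 * eps)
    chi_fd <- s / phi_sigma(m, s) * fd
    expect_lt(abs(chi(m, s) - chi_fd) / abs(chi_fd), 1e-4)
  }
  expect_identical(chi(-10, 0.1), 0)
})

test_that("moment_activate composes the element maps and the pair rule", {
  p <- lif_params()
  # diagonal input covariance -> identity output correlation
  cm <- current_moments(c(1, 2, 0.5), diag(c(1, 2, 0.5)))
  out <- moment_activate(cm)
  expect_equal(out$rho, diag(3))
  # two neurons at a common operating point: rho' = chi^2 * rho_bar
  rho_in <- 0.3
  S <- matrix(c(1, rho_in, rho_in, 1), 2)
  out2 <- moment_activate(current_moments(c(1.5, 1.5), S))
  ch <- chi(1.5, 1)
  expect_equal(out2$rho[1, 2], ch^2 * rho_in, tolerance = 1e-10)
  expect_equal(out2$mu, phi_mu(c(1.5, 1.5), 1))
  expect_equal(out2$Sigma[1, 1], phi_sigma(1.5, 1)^2, tolerance = 1e-12)
  expect_error(current_moments(c(1, 1), matrix(c(1, .2, .4, 1), 2)),
               "symmetric")
})

test_that("positive input correlation raises downstream rate (two-channel toy)", {
  # one downstream neuron summing two equally weighted inputs whose
  # correlation carries the class: mean drive identical, variance differs
  w <- 0.4
  mu_in <- c(1, 1)
  for (r in c(0.6, 0.3)) {
    Sp <- diag(mu_in) + 0.25 * matrix(c(1, r, r, 1), 2)
    Sm <- diag(mu_in) + 0.25 * matrix(c(1, -r, -r, 1), 2)
    W <- matrix(c(w, w), 1)
    mp <- moment_activate(synaptic_summation(W, list(mu = mu_in, Sigma = Sp)))
    mm <- moment_activate(synaptic_summation(W, list(mu = mu_in, Sigma = Sm)))
    expect_gt(mp$mu, mm$mu)
  }
})

test_that("correlation repair restores positive semidefiniteness", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(bad, symmetric = TRUE, only.values = TRUE)$values), 0)
  fixed <- momentcov:::.psd_repair_corr(bad)
  expect_gte(min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(diag(fixed), rep(1, 3))
  # a valid correlation passes through untouched
  ok <- matrix(c(1, 0.2, 0.2, 1), 2)
  expect_identical(momentcov:::.psd_repair_corr(ok), ok)
})
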