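test_that("log density decomposes additively and shares xi within a cell", {
  g <- grid_square(3)
  ax <- axis_small(4)
  spec <- lgcp_spec("SS3", ax)
  p <- lgcp_params(spec, mu = c(2, 1.5, 1, 0.5), sigma = 0.8,
                   sigma_eps = 0.6, delta = 1, a = 0.5)
  lat <- simulate_latent(g, spec, p, n_hauls = 6, seed = 5,
                         cells = c(1, 1, 2, 3, 4, 5))
  eta <- log_density(p, lat, haul = 1, class = 2)
  expect_equal(eta, p$mu[2] + lat$xi[2, 1] + lat$eps[[1]][2])
  ## hauls 1 and 2 share the cell, hence xi, but not eps
  d12 <- log_density(p, lat, 1, 3) - log_density(p, lat, 2, 3)
  expect_equal(d12, lat$eps[[1]][3] - lat$eps[[2]][3])
  ## zero latent state: eta reduces to mu
  p0 <- lgcp_params(spec, mu = 1:4, sigma = 0, sigma_eps = 0, delta = 1,
                    a = 0.5)
  lat0 <- simulate_latent(g, spec, p0, n_hauls = 2, seed = 5)
  expect_equal(log_density(p0, lat0, 1, 4), p0$mu[4])
  ## shifting mu by d and xi by -d leaves eta unchanged
  p2 <- p; p2$mu <- p$mu + 0.7
  lat2 <- lat; lat2$xi <- lat$xi - 0.7
  expect_equal(log_density(p2, lat2, 1, 2), eta)
  expect_error(log_density(p, lat, 99, 1), "haul")
  expect_error(log_density(p, lat, 1, 99), "class")
})

test_that("degenerate model reduces to the exact Poisson likelihood", {
  g <- grid_1()
  ax <- size_axis(10:12)
  spec <- lgcp_spec("SS2", ax)
  df <- data.frame(haul_id = rep(1:4, each = 3), cell = 1, year = 2009,
                   quarter = 4, species = "s", size_cm = rep(10:12, 4),
                   count = c(3, 1, 0, 5, 2, 1, 4, 0, 0, 2, 2, 1))
  dat <- haul_table(df)
  mu <- c(1.2, 0.3, -0.5)
  p <- lgcp_params(spec, mu = mu, sigma = 1e-9, sigma_eps = 1e-9,
                   delta = 1, a = 2)
  exact <- -sum(stats::dpois(df$count, exp(mu[df$size_cm - 9]), log = TRUE))
  expect_equal(nll_laplace(p, dat, g, spec), exact, tolerance = 1e-7)
  ## and the Poisson MLE of mu is log of the class mean
  fit <- suppressWarnings(lgcp_fit(dat, g, spec, control =
    lgcp_control(se = FALSE)))
  cpue <- tapply(df$count, df$size_cm, mean)
  ## with latent variance estimated near zero the means track log CPUE
  expect_true(stats::cor(fit$estimates$mu, log(as.numeric(cpue))) > 0.99)
})

test_that("Laplace NLL agrees with 1-D quadrature for one haul, one class", {
  g <- grid_1()
  ax <- size_axis(10)
  spec <- lgcp_spec("SS2", ax)
  quad <- function(y, mu, s) {
    f <- function(t) exp(y * (mu + t) - exp(mu + t) - lgamma(y + 1)) *
      stats::dnorm(t, 0, s)
    -log(stats::integrate(f, -12 * s, 12 * s, rel.tol = 1e-12)$value)
  }
  for (y in c(0, 2, 7)) {
    dat <- haul_table(data.frame(haul_id = 1, cell = 1, year = 2009,
                                 quarter = 4, species = "s", size_cm = 10,
                                 count = y))
    for (sig in c(0.1, 0.2)) {
      p <- lgcp_params(spec, mu = 0.8, sigma = sig, sigma_eps = 0.1,
                       delta = 1, a = 2)
      expect_equal(nll_laplace(p, dat, g, spec),
                   quad(y, 0.8, sqrt(sig^2 + 0.01)), tolerance = 1e-3)
    }
  }
})

test_that("NLL is permutation invariant and respects model nesting", {
  fx <- sim_small_survey(seed = 2, n_hauls = 40, n = 3, k = 4)
  p <- fx$truth
  base <- nll_laplace(p, fx$data, fx$grid, fx$spec)
  ## shuffle record order
  df <- as.data.frame(fx$data)
  set.seed(1)
  dat2 <- haul_table(df[sample(nrow(df)), ], width = 2)
  expect_equal(nll_laplace(p, dat2, fx$grid, fx$spec), base,
               tolerance = 1e-9)

  ## super-model attains at least the sub-model optimum: fit SS2 (natural
  ## scale) and SS1 (unconstrained) on the same data
  ctrl <- lgcp_control(se = FALSE)
  f_ss3 <- suppressWarnings(lgcp_fit(fx$data, fx$grid, fx$spec,
                                     control = ctrl))
  spec1 <- lgcp_spec("SS1", fx$axis)
  f_ss1 <- suppressWarnings(lgcp_fit(fx$data, fx$grid, spec1,
                                     control = ctrl))
  expect_lte(f_ss1$nll, f_ss3$nll + 1e-4)
})

test_that("latent mode has zero gradient, PD curvature, shrinkage sign", {
  g <- grid_1()
  ax <- size_axis(10)
  spec <- lgcp_spec("SS2", ax)
  dat <- haul_table(data.frame(haul_id = 1, cell = 1, year = 2009,
                               quarter = 4, species = "s", size_cm = 10,
                               count = 0))
  p <- lgcp_params(spec, mu = 2, sigma = 1, sigma_eps = 0.5, delta = 1,
                   a = 2)
  lm <- latent_mode(p, dat, g, spec)
  expect_lt(lm$grad_norm, 1e-8)
  expect_true(lm$hessian_pd)
  ## zero counts against a large mean: the mode is pulled negative
  expect_lt(lm$xi[1, 1], 0)
  expect_lt(lm$eps[1], 0)
  ## 1-D oracle: stationarity of the joint negative log posterior gives
  ## xi = -sigma * lambda and eps = -sigma_eps * lambda at lambda = exp(eta)
  lambda <- exp(2 + lm$xi[1, 1] + 0.5 * lm$eps[1])
  expect_equal(lm$xi[1, 1], -1 * lambda, tolerance = 1e-6)
  expect_equal(lm$eps[1], -0.5 * lambda, tolerance = 1e-6)
})

test_that("fit is stationary at its optimum and means track CPUE", {
  fx <- sim_small_survey(seed = 3, n_hauls = 60, n = 4, k = 5)
  fit <- suppressWarnings(lgcp_fit(fx$data, fx$grid, fx$spec))
  expect_equal(fit$convergence$code, 0)
  ## refit from the optimum barely moves
  refit <- suppressWarnings(lgcp_fit(fx$data, fx$grid, fx$spec,
                                     init = fit$estimates,
                                     control = lgcp_control(se = FALSE)))
  expect_lt(abs(refit$nll - fit$nll), 1e-4)
  ## exp(mu) is monotonically related to spatially averaged counts (CPUE)
  cpue <- tapply(fx$data$count, fx$data$size_cm, mean)
  expect_gte(stats::cor(fit$estimates$mu, log(as.numeric(cpue)),
                        method = "spearman"), 0.89)
})
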