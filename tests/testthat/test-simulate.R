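test_that("latent draws are reproducible and respect magnitudes", {
  g <- grid_square(2)
  ax <- axis_small(2)
  spec <- lgcp_spec("SS2", ax)
  p <- lgcp_params(spec, sigma = 0.7, sigma_eps = 0.4, delta = 1, a = 4)
  l1 <- simulate_latent(g, spec, p, n_hauls = 5, seed = 11)
  l2 <- simulate_latent(g, spec, p, n_hauls = 5, seed = 11)
  expect_identical(l1, l2)
  l3 <- simulate_latent(g, spec, p, n_hauls = 5, seed = 12)
  expect_false(identical(l1$xi, l3$xi))
  ## sigma = 0 gives a null field
  p0 <- lgcp_params(spec, sigma = 0, sigma_eps = 0.4, delta = 1, a = 4)
  expect_equal(simulate_latent(g, spec, p0, 3, seed = 1)$xi,
               matrix(0, 2, 4))
  expect_error(simulate_latent(g, spec, p, 0), "n_hauls")
})

test_that("sample covariance of the field matches its target", {
  ## 2 cells x 2 classes: 4-dimensional field, closed-form covariance
  g <- grid_strip(2)
  ax <- axis_small(2)
  spec <- lgcp_spec("SS2", ax)
  p <- lgcp_params(spec, sigma = 1, sigma_eps = 0.5, delta = 1, a = 4,
                   b = 0, c = 0)
  target <- materialize_joint(spatial_correlation(g, 1),
                              spec_joint_corr(spec, p), sigma = 1)
  set.seed(99)
  X <- t(replicate(2000, as.numeric(
    simulate_latent(g, spec, p, n_hauls = 1)$xi)))
  emp <- stats::cov(X)
  expect_lt(norm(emp - target, "F") / norm(target, "F"), 0.05)
})

test_that("simulated surveys show zeros, over-dispersion, mean structure", {
  g <- grid_1()
  ax <- size_axis(10)
  spec <- lgcp_spec("SS2", ax)
  ## lognormal-mixture mean: E[count] = exp(mu + tau2/2).  On a 1-cell grid
  ## each survey shares a single field draw, so the expectation is taken
  ## over repeated surveys (200 surveys x 50 hauls = 1e4 hauls) and the
  ## check uses the Monte-Carlo standard error across surveys
  p <- lgcp_params(spec, mu = 1, sigma = 0.6, sigma_eps = 0.5, delta = 1,
                   a = 2)
  m_r <- vapply(seq_len(200), function(r)
    mean(simulate_survey(g, spec, p, n_hauls = 50, seed = 1000 + r)$count),
    0)
  tau2 <- 0.6^2 + 0.5^2
  se <- stats::sd(m_r) / sqrt(length(m_r))
  expect_lt(abs(mean(m_r) - exp(1 + tau2 / 2)), 3 * se)
  ## variance exceeds mean (over-dispersion from the lognormal mixing)
  dat <- simulate_survey(g, spec, p, n_hauls = 10000, seed = 17)
  expect_gt(stats::var(dat$count), mean(dat$count))

  ## a very negative mean produces almost all no-catch records
  pz <- lgcp_params(spec, mu = -4, sigma = 0.6, sigma_eps = 0.5, delta = 1,
                    a = 2)
  datz <- simulate_survey(g, spec, pz, n_hauls = 300, seed = 2)
  expect_gt(mean(datz$count == 0), 0.95)
  expect_true(any(datz$count == 0))

  ## identical seeds give identical tables
  fx1 <- simulate_survey(g, spec, p, 50, seed = 4)
  fx2 <- simulate_survey(g, spec, p, 50, seed = 4)
  expect_identical(fx1, fx2)
})

test_that("year-joint surveys split hauls and classes by year", {
  g <- grid_square(3)
  spec <- lgcp_spec("MY3", axis_small(3), groups = c("2009", "2010"))
  p <- lgcp_params(spec, mu = 1, rho = 0.5, a = 0.4)
  dat <- simulate_survey(g, spec, p, n_hauls = 30, seed = 6)
  expect_setequal(unique(dat$year), c("2009", "2010"))
  ## each haul observes one year's classes only
  per_haul <- tapply(dat$year, dat$haul_id, function(v) length(unique(v)))
  expect_true(all(per_haul == 1))
  expect_equal(nrow(dat), 30 * 3)
})

test_that("recovery summaries have the documented shape and fail loudly", {
  fx <- sim_small_survey(seed = 5)
  rec <- recovery_experiment(fx$spec, fx$grid, fx$truth, n_hauls = 60,
                             n_replicates = 2, seed = 3,
                             control = lgcp_control())
  expect_setequal(rec$summary$parameter,
                  c("sigma", "sigma_eps", "delta", "a", "b", "c"))
  expect_true(all(c("truth", "bias", "rmse", "coverage") %in%
                  names(rec$summary)))
  expect_equal(rec$n_converged + rec$n_failed, 2L)
  expect_error(recovery_experiment(fx$spec, fx$grid, fx$truth, 60, 0, 1),
               "n_replicates")
})
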