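test_that("surfaces revert to the stationary level away from data", {
  fx <- sim_small_survey(seed = 8, n_hauls = 50, n = 4, k = 4)
  fit <- suppressWarnings(lgcp_fit(fx$data, fx$grid, fx$spec,
                                   control = lgcp_control(se = FALSE)))
  ## conditioning on nothing: flat surface exp(mean of mu over classes)
  empty <- fx$data[0, ]
  s0 <- predict_surface(fit, data = empty)
  expect_equal(unique(round(s0$value, 12)),
               exp(mean(fit$estimates$mu)))

  ## one extreme haul in cell 1: that cell's surface rises above the
  ## stationary level; remote cells stay near it
  g <- grid_strip(8)
  ax <- size_axis(10)
  spec <- lgcp_spec("SS2", ax)
  one <- haul_table(data.frame(haul_id = 1, cell = 1, year = 2009,
                               quarter = 4, species = "s", size_cm = 10,
                               count = 60))
  p <- lgcp_params(spec, mu = 1, sigma = 0.8, sigma_eps = 0.3,
                   delta = 0.3, a = 2)
  fit1 <- suppressWarnings(lgcp_fit(one, g, spec, init = p,
    control = lgcp_control(maxit = 0, se = FALSE)))
  s1 <- predict_surface(fit1)
  level <- exp(fit1$estimates$mu)
  expect_gt(s1$value[1], level)
  ## monotone reversion toward exp(mu) with water distance from the haul
  expect_true(all(diff(s1$value) < 0))
  expect_lt(abs(s1$value[8] - level) / level,
            abs(s1$value[1] - level) / level)
})

test_that("cross-prediction is flat under independence, informative under
           strong coupling", {
  g <- grid_square(4)
  ax <- axis_small(3)
  spec0 <- lgcp_spec("MS4", ax, groups = c("cod", "whiting"))
  p0 <- lgcp_params(spec0, mu = 1.5, sigma = 0.8, sigma_eps = 0.5,
                    delta = 1, a = 0.4, b = 2, c = 0.5)
  dat <- simulate_survey(g, spec0, p0, n_hauls = 60, seed = 9)
  fit0 <- suppressWarnings(lgcp_fit(dat, g, spec0,
                                    control = lgcp_control(se = FALSE)))
  cp <- cross_predict(fit0, group = "cod")
  mu_cod <- fit0$estimates$mu[1:3]
  expect_equal(unique(round(cp$value, 10)), exp(mean(mu_cod)))

  ## empty auxiliary data: flat prior surface with a warning
  aux0 <- dat[0, ]
  expect_warning(cp0 <- cross_predict(fit0, group = "cod",
                                      aux_data = aux0), "empty")
  expect_equal(unique(round(cp0$value, 10)), exp(mean(mu_cod)))

  ## strongly coupled years: cross-prediction tracks direct prediction
  specy <- lgcp_spec("MY3", ax, groups = c("2009", "2010"))
  py <- lgcp_params(specy, mu = 2, sigma = 1, sigma_eps = 0.4, delta = 0.5,
                    a = 0.4, b = 2, c = 0.5, rho = 0.95)
  daty <- simulate_survey(g, specy, py, n_hauls = 160, seed = 10)
  fity <- suppressWarnings(lgcp_fit(daty, g, specy,
                                    control = lgcp_control(se = FALSE)))
  direct <- predict_surface(fity, group = "2010")
  crossp <- cross_predict(fity, group = "2010")  # from 2009 hauls only
  expect_gt(stats::cor(direct$value, crossp$value, method = "spearman"),
            0.5)
})

test_that("conditioning on more data never inflates conditional variance", {
  ## Gaussian conditional-variance oracle on a small dense instance
  g <- grid_strip(3)
  S <- spatial_correlation(g, delta = 1)
  C <- random_corr(2)
  V <- materialize_joint(S, C, sigma = 0.9)
  idx_small <- 1:2          # observe field at cell 1 (both classes)
  idx_big <- 1:4            # observe cells 1 and 2
  cond_var <- function(V, obs) {
    noise <- diag(0.3, length(obs))
    V[5:6, 5:6] - V[5:6, obs] %*%
      solve(V[obs, obs] + noise, t(V[5:6, obs, drop = FALSE]))
  }
  v1 <- diag(cond_var(V, idx_small))
  v2 <- diag(cond_var(V, idx_big))
  expect_true(all(v2 <= v1 + 1e-12))
  expect_true(all(v1 <= diag(V)[5:6] + 1e-12))
})

test_that("surface containers serialize and plot", {
  fx <- sim_small_survey(seed = 12, n_hauls = 30, n = 3, k = 3)
  fit <- suppressWarnings(lgcp_fit(fx$data, fx$grid, fx$spec,
                                   control = lgcp_control(se = FALSE)))
  s <- predict_surface(fit, sizes = c(6, 8))
  expect_s3_class(s, "lgcp_surface")
  expect_true(all(s$value >= 0))
  expect_equal(nrow(s), 9)
  tf <- tempfile(fileext = ".tsv")
  write_surface(s, tf)
  back <- utils::read.delim(tf)
  expect_equal(back$value, s$value, tolerance = 1e-12)
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf, 300, 300)
  expect_silent(plot(s))
  grDevices::dev.off()
  expect_true(file.size(pf) > 0)
})
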