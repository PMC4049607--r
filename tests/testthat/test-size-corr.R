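test_that("size axis and transforms behave as documented", {
  ax <- size_axis(c(10, 20), width = 1)
  expect_equal(ax$midpoints, c(10.5, 20.5))
  expect_equal(transform_sizes(ax), c(10.5, 20.5))

  ## log scale: equal ratios give equal distances
  ax4 <- size_axis(c(10, 20, 40) - 0.5, width = 1)  # midpoints 10, 20, 40
  t <- transform_sizes(ax4, size_transform("log"))
  expect_equal(t[2] - t[1], t[3] - t[2])

  ## logistic maps L50 to 1/2 and into (0, 1)
  ax5 <- size_axis(c(10, 19.5, 30), width = 1)      # midpoint 20 at centre
  tl <- transform_sizes(ax5, size_transform("logistic", L50 = 20, alpha = 0.5))
  expect_equal(tl[2], 0.5)
  expect_true(all(tl > 0 & tl < 1))
  expect_true(all(diff(tl) > 0))

  expect_error(transform_sizes(size_axis(-3), size_transform("log")),
               "positive")
  expect_error(size_transform("logistic"), "L50")
})

test_that("oscillating correlation: normalization, closed form, negativity", {
  expect_equal(oscillating_correlation(0, a = 1.3, b = 2, c = 0.7), 1)
  expect_equal(oscillating_correlation(2, a = 2, b = 0, c = 3), exp(-1),
               tolerance = 1e-12)
  ## pure exponential decay at b = 0, strictly decreasing
  d <- seq(0, 5, by = 0.25)
  v <- oscillating_correlation(d, a = 1.5, b = 0, c = 0.4)
  expect_true(all(diff(v) < 0))
  ## with b > 0 and small c the correlation goes negative for some distance
  v2 <- oscillating_correlation(seq(0, 10, by = 0.05), a = 4, b = 1, c = 0.1)
  expect_true(any(v2 < 0))
  expect_error(oscillating_correlation(-1, a = 1), "non-negative")
  expect_error(oscillating_correlation(1, a = -1), "positive")
})

test_that("size correlation matrix matches brute-force evaluation", {
  ax <- size_axis(1:15)
  tr <- size_transform("log")
  M <- size_corr_matrix(ax, tr, a = 2, b = 1, c = 1)
  expect_equal(dim(M), c(15L, 15L))
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 15))
  t <- transform_sizes(ax, tr)
  for (i in c(1, 4, 15)) for (j in c(2, 9))
    expect_equal(M[i, j],
                 oscillating_correlation(abs(t[i] - t[j]), a = 2, b = 1,
                                         c = 1))
  expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(size_corr_matrix(size_axis(10), a = 1), matrix(1))

  ## b = 0 on the natural scale: Toeplitz geometric decay across 1-cm bins
  Mt <- size_corr_matrix(size_axis(1:6), size_transform("identity"), a = 2)
  expect_equal(Mt, outer(1:6, 1:6, function(i, j) exp(-abs(i - j) / 2)))
})

test_that("all structured size correlations are PD across random draws", {
  set.seed(11)
  worst <- Inf
  for (r in 1:60) {
    k <- sample(2:45, 1)
    width <- sample(c(1, 2), 1)
    ax <- size_axis(seq(4, by = width, length.out = k), width = width)
    tr <- switch(sample(3, 1),
                 size_transform("identity"),
                 size_transform("log"),
                 size_transform("logistic", L50 = stats::runif(1, 5, 40),
                                alpha = stats::runif(1, 0.05, 1)))
    M <- size_corr_matrix(ax, tr, a = stats::runif(1, 0.05, 10),
                          b = stats::runif(1, 0, 6),
                          c = stats::runif(1, 0, 4))
    worst <- min(worst,
                 min(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
  }
  expect_gte(worst, -1e-10)
})

test_that("hyperspherical map is a bijection onto PD correlations", {
  expect_equal(unconstrained_corr(rep(0, 15), 6), diag(6))
  expect_equal(unconstrained_corr(numeric(0), 1), matrix(1))
  expect_error(unconstrained_corr(1:4, 4), "length")

  ## k = 2: single parameter sweeps (-1, 1) monotonically
  th <- seq(-6, 6, length.out = 25)
  r <- vapply(th, function(t) unconstrained_corr(t, 2)[1, 2], 0)
  expect_true(all(diff(r) < 0))   # angle grows with theta, cosine falls
  expect_true(all(r > -1 & r < 1))
  ## closed form: corr = cos(pi * plogis(theta))... sign convention: large
  ## theta -> angle near pi -> correlation near -1
  expect_equal(r[1], cos(pi / (1 + exp(6))), tolerance = 1e-12)

  ## round trip through the inverse map
  set.seed(3)
  for (k in c(3, 5, 9)) {
    C0 <- random_corr(k)
    th0 <- corr_to_theta(C0)
    expect_equal(unconstrained_corr(th0, k), C0, tolerance = 1e-10)
  }
  ## PD for random parameters
  for (r in 1:20) {
    k <- sample(2:12, 1)
    C <- unconstrained_corr(stats::rnorm(k * (k - 1) / 2, sd = 2), k)
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(diag(C), rep(1, k))
  }
})

test_that("rebinning sums counts and conserves totals", {
  df <- data.frame(haul_id = rep(1:2, each = 4), cell = 1, year = 2009,
                   quarter = 4, species = "cod", size_cm = rep(10:13, 2),
                   count = c(1, 2, 3, 4, 5, 0, 2, 1))
  ht <- haul_table(df)
  r2 <- rebin_counts(ht, 2)
  expect_equal(attr(r2, "width"), 2)
  expect_equal(r2$count[r2$haul_id == 1], c(3, 7))
  expect_equal(r2$count[r2$haul_id == 2], c(5, 3))
  expect_equal(sum(r2$count), sum(ht$count))
  expect_identical(rebin_counts(ht, 1), ht)
  expect_error(rebin_counts(r2, 3), "multiple")  # 3 not a multiple of 2
})
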