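## shared fixtures: tiny grids, axes and simulated surveys built in code

grid_1 <- function() build_lattice(matrix(TRUE, 1, 1))
grid_strip <- function(n) build_lattice(matrix(TRUE, 1, n))
grid_square <- function(n) build_lattice(matrix(TRUE, n, n))

## 5x5 grid with a land wall along column 3, one gap at row 3
grid_wall <- function() {
  m <- matrix(TRUE, 5, 5)
  m[c(1, 2, 4, 5), 3] <- FALSE
  build_lattice(m)
}

axis_small <- function(k = 5, width = 2) size_axis(seq(6, by = width,
                                                       length.out = k),
                                                   width = width)

## random PD correlation matrix via the hyperspherical map
random_corr <- function(k, sd = 0.8) {
  unconstrained_corr(stats::rnorm(k * (k - 1) / 2, sd = sd), k)
}

## importance-sampling estimate of the exact marginal NLL for a small
## single-group model (all hauls observe all classes), using the Laplace
## Gaussian at the latent mode as proposal
is_nll_oracle <- function(params, data, grid, spec, n_draws = 1e4) {
  lm <- latent_mode(params, data, grid, spec)
  K <- nrow(lm$xi); M <- ncol(lm$xi)
  m <- c(as.numeric(lm$xi), lm$eps)
  H <- as.matrix(lm$hessian)
  n <- length(m)
  L <- chol(H)                              # H = t(L) %*% L, L upper
  Z <- matrix(stats::rnorm(n * n_draws), n)
  U <- m + backsolve(L, Z)                  # draws from N(m, H^-1)
  logq <- sum(log(diag(L))) - n / 2 * log(2 * pi) -
    0.5 * colSums((L %*% (U - m))^2)

  ## joint log density log p(y, u) per draw
  S <- spatial_correlation(grid, params$delta, spec$kappa)
  C <- spec_joint_corr(spec, params)
  V <- kronecker(S, C)                      # vec(xi), class fastest
  Lv <- chol(V)
  Lc <- chol(C)
  df <- as.data.frame(data)
  hauls <- unique(df[, c("haul_id", "cell")])
  hauls <- hauls[order(hauls$haul_id), ]
  hi <- match(df$haul_id, hauls$haul_id)
  ci <- match(df$size_cm, spec$axis$lower)
  nh <- nrow(hauls)
  Xi <- U[seq_len(K * M), , drop = FALSE]
  Ep <- U[K * M + seq_len(K * nh), , drop = FALSE]
  logp <- -0.5 * colSums(backsolve(Lv, Xi, transpose = TRUE)^2) -
    sum(log(diag(Lv))) - K * M / 2 * log(2 * pi)
  for (h in seq_len(nh)) {
    Eh <- Ep[(h - 1) * K + seq_len(K), , drop = FALSE]
    logp <- logp - 0.5 * colSums(backsolve(Lc, Eh, transpose = TRUE)^2) -
      sum(log(diag(Lc))) - K / 2 * log(2 * pi)
  }
  for (r in seq_len(nrow(df))) {
    eta <- params$mu[ci[r]] +
      params$sigma * Xi[(df$cell[r] - 1) * K + ci[r], ] +
      params$sigma_eps * Ep[(hi[r] - 1) * K + ci[r], ]
    logp <- logp + df$count[r] * eta - exp(eta) - lgamma(df$count[r] + 1)
  }
  w <- logp - logq
  mx <- max(w)
  -(mx + log(mean(exp(w - mx))))
}

## small single-species survey used across tests
sim_small_survey <- function(seed = 1, n_hauls = 80, n = 4, k = 5) {
  g <- grid_square(n)
  ax <- axis_small(k)
  spec <- lgcp_spec("SS3", ax)
  truth <- lgcp_params(spec, mu = seq(3, 1, length.out = k), sigma = 0.8,
                       sigma_eps = 0.6, delta = 1, a = 0.98, b = 2.42,
                       c = 0.35)
  list(grid = g, axis = ax, spec = spec, truth = truth,
       data = simulate_survey(g, spec, truth, n_hauls, seed = seed))
}
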