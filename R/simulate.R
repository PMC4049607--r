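## haul -> period/group assignment used by the simulator: species-joint
## surveys observe both species in every haul; year-joint surveys split the
## hauls evenly between the two years
sim_haul_layout <- function(spec, n_hauls) {
  if (spec$role == "year") {
    yr <- rep_len(1:2, n_hauls)
    list(block = yr, year = spec$groups[yr])
  } else {
    list(block = rep.int(1L, n_hauls),
         year = rep.int("2009", n_hauls))
  }
}

#' Draw the latent fields of the model
#'
#' Samples the structured spatial-size field `xi` from the zero-mean
#' Gaussian with covariance `sigma^2 (S (x) C)` (spatial correlation `S`
#' over water cells, joint correlation `C` over classes) and, per haul, a
#' nugget vector from `sigma_eps^2` times the size/joint correlation of the
#' classes the haul observes.
#'
#' @param grid a [build_lattice()] lattice
#' @param spec an [lgcp_spec()]
#' @param params an [lgcp_params()] (simulation truth)
#' @param n_hauls number of hauls to draw nuggets for
#' @param seed integer seed (reproducible draws)
#' @param cells optional water-cell id per haul (default: uniform over water)
#' @return list with `xi` (K x M matrix, scaled by `sigma`), `eps` (list of
#'   per-haul scaled nugget vectors), `hauls` (cell/block assignment)
#' @export
simulate_latent <- function(grid, spec, params, n_hauls, seed = NULL,
                            cells = NULL) {
  if (n_hauls < 1) stop("'n_hauls' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  M <- n_cells(grid)
  K <- spec_k(spec)
  S <- spatial_correlation(grid, params$delta, spec$kappa)
  C <- spec_joint_corr(spec, params)
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop("joint correlation factor is not positive definite")
  Lc <- t(chol_psd(C))
  Rs <- chol(S)
  ## X = Lc Z Rs has vec(X) ~ N(0, S (x) C), columns indexed by cell
  Z <- matrix(stats::rnorm(K * M), K, M)
  xi <- params$sigma * (Lc %*% Z %*% Rs)

  if (is.null(cells)) cells <- sample.int(M, n_hauls, replace = TRUE)
  lay <- sim_haul_layout(spec, n_hauls)
  kA <- n_classes(spec$axis)
  block_idx <- if (spec$role == "year")
    list(seq_len(kA), (kA + 1L):K) else list(seq_len(K))
  Lb <- lapply(block_idx, function(ix) t(chol_psd(C[ix, ix, drop = FALSE])))
  eps <- lapply(seq_len(n_hauls), function(h) {
    L <- Lb[[lay$block[h]]]
    as.numeric(params$sigma_eps * (L %*% stats::rnorm(nrow(L))))
  })
  list(xi = xi, eps = eps,
       hauls = data.frame(haul = seq_len(n_hauls), cell = cells,
                          block = lay$block, year = lay$year))
}

## Cholesky tolerant of tiny negative eigenvalues (boundary correlations)
chol_psd <- function(A) {
  out <- try(chol(A), silent = TRUE)
  if (!inherits(out, "try-error")) return(out)
  e <- eigen(A, symmetric = TRUE)
  vals <- pmax(e$values, 1e-10)
  chol(e$vectors %*% (vals * t(e$vectors)))
}

#' Simulate a synthetic trawl survey
#'
#' Generates haul-level counts with exactly the statistical structure the
#' model assumes: haul positions uniform over water cells, latent fields
#' from [simulate_latent()], and counts Poisson with mean
#' `exp(mu_s + xi(s, cell) + eps(haul, s))`.  Zero counts are retained, and
#' the marginal counts are over-dispersed relative to Poisson (lognormal
#' mixing).
#'
#' @inheritParams simulate_latent
#' @return a [haul_table()] with positions at cell centres
#' @export
simulate_survey <- function(grid, spec, params, n_hauls, seed = NULL) {
  lat <- simulate_latent(grid, spec, params, n_hauls, seed)
  K <- spec_k(spec)
  kA <- n_classes(spec$axis)
  gidx <- spec_group_of_class(spec)
  lower <- c(spec$axis$lower, if (spec$joint) spec$axis_b$lower)
  species <- switch(spec$role,
    species = spec$groups[gidx],
    year = rep.int("A", K),
    single = rep.int(spec$groups %||% "A", K))

  cls_of <- function(h) {
    if (spec$role != "year") seq_len(K)
    else if (lat$hauls$block[h] == 1L) seq_len(kA) else (kA + 1L):K
  }
  H <- nrow(lat$hauls)
  cls <- unlist(lapply(seq_len(H), cls_of))
  len <- if (spec$role == "year")
    ifelse(lat$hauls$block == 1L, kA, K - kA) else rep.int(K, H)
  hid <- rep.int(seq_len(H), len)
  cell <- lat$hauls$cell[hid]
  eta <- params$mu[cls] + lat$xi[cbind(cls, cell)] +
    unlist(lat$eps, use.names = FALSE)
  df <- data.frame(
    haul_id = hid, cell = cell,
    year = if (spec$role == "year") lat$hauls$year[hid] else "2009",
    quarter = 4L,
    species = species[cls],
    size_cm = lower[cls],
    count = stats::rpois(length(cls), exp(eta))
  )
  ctr <- cell_centres(grid)
  df$x <- ctr[df$cell, "x"]
  df$y <- ctr[df$cell, "y"]
  haul_table(df, width = spec$axis$width)
}

#' Parameter-recovery experiment
#'
#' Simulates surveys from known truth, refits the model, and summarizes
#' per-parameter bias, root-mean-square error and the coverage of
#' `+/- 1.96 SE` Wald intervals across replicates.  Intervals are formed on
#' the estimation scale (log for positive parameters, `atanh` for the group
#' correlation), the standard Wald construction for parameters with skewed
#' sampling distributions.  Replicates whose fit fails to converge (or
#' whose observed information is not positive definite) are excluded and
#' counted.
#'
#' @inheritParams simulate_latent
#' @param n_replicates number of simulated surveys
#' @param control fitting options, see [lgcp_control()]
#' @return list with `summary` (one row per covariance parameter: truth,
#'   mean estimate, bias, rmse, coverage), `n_converged`, `n_failed`
#' @export
recovery_experiment <- function(spec, grid, params, n_hauls, n_replicates,
                                seed = 1, control = lgcp_control()) {
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  truth <- NULL
  est <- list(); ses <- list(); failed <- 0L
  for (r in seq_len(n_replicates)) {
    dat <- simulate_survey(grid, spec, params, n_hauls, seed = seed + r)
    fit <- suppressWarnings(
      try(lgcp_fit(dat, grid, spec, control = control), silent = TRUE))
    ok <- !inherits(fit, "try-error") && fit$convergence$code == 0 &&
      !is.null(fit$se) && isTRUE(fit$convergence$pdHess)
    if (!ok) { failed <- failed + 1L; next }
    v <- fit_param_vector(fit)
    s <- fit$se_fixed[transformed_name(names(v))]
    if (anyNA(s)) { failed <- failed + 1L; next }
    est[[length(est) + 1L]] <- v
    ses[[length(ses) + 1L]] <- s
  }
  if (length(est) == 0L) stop("no replicate converged")
  E <- do.call(rbind, est)
  SE <- do.call(rbind, ses)
  tp <- lgcp_params(spec, mu = params$mu, sigma = params$sigma,
                    sigma_eps = params$sigma_eps, delta = params$delta,
                    a = params$a, b = params$b, c = params$c,
                    L50 = params$L50, alpha = params$alpha,
                    rho = params$rho %||% 0, R = params$R,
                    theta = params$theta)
  fake <- list(estimates = tp)
  truth <- fit_param_vector(fake)[colnames(E)]
  Tfun <- function(x, nm) ifelse(startsWith(nm, "rho"), atanh(x),
                                 log(pmax(x, 1e-12)))
  Tdiff <- abs(t(apply(E, 1, Tfun, nm = colnames(E))) -
               rep(Tfun(truth, colnames(E)), each = nrow(E)))
  cover <- colMeans(Tdiff <= 1.96 * SE)
  list(
    summary = data.frame(
      parameter = colnames(E),
      truth = truth,
      mean_est = colMeans(E),
      median_est = apply(E, 2, stats::median),
      bias = colMeans(E) - truth,
      rmse = sqrt(colMeans(sweep(E, 2, truth)^2)),
      coverage = cover,
      row.names = NULL
    ),
    n_converged = length(est),
    n_failed = failed
  )
}
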