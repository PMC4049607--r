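## ---- TMB glue -------------------------------------------------------------

tmb_data <- function(spec, grid, idx) {
  ed <- lattice_edges(grid)
  list(
    M = n_cells(grid),
    nn = as.integer(grid$n_neighbours),
    edge_i = as.integer(ed[, "i"] - 1L),
    edge_j = as.integer(ed[, "j"] - 1L),
    kappa = spec$kappa,
    K = as.integer(idx$K),
    kA = as.integer(n_classes(spec$axis)),
    class_group = as.integer(spec_group_of_class(spec) - 1L),
    class_size = spec_class_sizes(spec),
    transform_code = match(spec$transform,
                           c("identity", "log", "logistic")) - 1L,
    size_code = as.integer(spec$size_model == "unconstrained"),
    cross_code = if (!spec$joint) 0L else
      match(spec$cross_model, c("independent", "separable", "unconstrained")),
    osc_index = as.integer(osc_index(spec)),
    haul_block = as.integer(idx$haul_block - 1L),
    eps_off = as.integer(idx$eps_off),
    block_start = as.integer(idx$block_start),
    block_len = as.integer(idx$block_len),
    obs_class = as.integer(idx$obs_class),
    obs_cell = as.integer(idx$obs_cell),
    obs_eps = as.integer(idx$obs_eps),
    obs_count = as.numeric(idx$obs_count)
  )
}

tmb_pars <- function(spec, params, dat) {
  n_eps <- sum(dat$block_len[dat$haul_block + 1L])
  floor_log <- function(x) log(pmax(x, 1e-8))
  list(
    mu = params$mu,
    log_sigma = floor_log(params$sigma),
    log_sigma_eps = floor_log(params$sigma_eps),
    log_delta = log(params$delta),
    log_a = log(params$a),
    log_b = floor_log(params$b),
    log_c = floor_log(params$c),
    L50 = params$L50 %||% 0,
    log_alpha = log(params$alpha %||% 1),
    theta = params$theta %||% 0,
    Rvec = if (is.null(params$R)) 0 else as.numeric(params$R),
    rho_t = atanh(min(max(params$rho %||% 0, -0.999), 0.999)),
    xi = rep(0, dat$K * dat$M),
    eps = rep(0, n_eps)
  )
}

tmb_map <- function(spec) {
  map <- list()
  if (spec$transform != "logistic") {
    map$L50 <- factor(NA); map$log_alpha <- factor(NA)
  }
  if (spec$size_model != "unconstrained") map$theta <- factor(NA)
  if (!spec$joint || spec$cross_model != "unconstrained")
    map$Rvec <- factor(NA)
  if (!spec$joint || spec$cross_model != "separable")
    map$rho_t <- factor(NA)
  if (spec$joint && spec$cross_model == "unconstrained") {
    kA <- n_classes(spec$axis); kB <- n_classes(spec$axis_b)
    map$Rvec <- factor(seq_len(kA * kB))
  }
  if (spec$size_model == "unconstrained") {
    k <- n_classes(spec$axis)
    map$theta <- factor(seq_len(k * (k - 1) / 2))
  }
  map
}

make_obj <- function(data, grid, spec, params, profile_mu = FALSE,
                     inner_tol = 1e-8, inner_maxit = 100) {
  idx <- index_haul_table(data, spec)
  dat <- tmb_data(spec, grid, idx)
  pars <- tmb_pars(spec, params, dat)
  obj <- TMB::MakeADFun(
    data = dat, parameters = pars, map = tmb_map(spec),
    random = c("xi", "eps"),
    profile = if (profile_mu) "mu",
    DLL = "sizestructLGCP", silent = TRUE
  )
  obj$env$inner.control$tol <- inner_tol
  obj$env$inner.control$maxit <- inner_maxit
  attr(obj, "idx") <- idx
  attr(obj, "dat") <- dat
  obj
}

## box constraints on the optimised (transformed) parameters
par_bounds <- function(nm) {
  lo <- c(mu = -20, log_sigma = -7, log_sigma_eps = -7, log_delta = -7,
          log_a = -6, log_b = -9, log_c = -9, L50 = 0.1, log_alpha = -5,
          theta = -12, Rvec = -30, rho_t = -7)
  hi <- c(mu = 20, log_sigma = 3, log_sigma_eps = 3, log_delta = 6,
          log_a = 6, log_b = 4, log_c = 6, L50 = 200, log_alpha = 3,
          theta = 12, Rvec = 30, rho_t = 7)
  list(lower = unname(lo[nm]), upper = unname(hi[nm]))
}

#' Fitting options
#'
#' @param profile_mu move the nuisance means `mu` into the inner
#'   optimisation.  This shrinks the outer problem when the number of size
#'   classes is large, but omits the means' contribution to the Laplace
#'   curvature correction, so the optimised objective differs slightly from
#'   the exact joint maximum; the default optimises `mu` jointly
#' @param maxit outer iteration limit
#' @param rel_tol outer relative convergence tolerance
#' @param inner_tol,inner_maxit gradient tolerance and iteration cap of the
#'   inner Newton optimisation for the latent mode
#' @param se compute standard errors (via [TMB::sdreport()])
#' @return list of options for [lgcp_fit()]
#' @export
lgcp_control <- function(profile_mu = FALSE, maxit = 500, rel_tol = 1e-8,
                         inner_tol = 1e-8, inner_maxit = 100, se = TRUE) {
  list(profile_mu = profile_mu, maxit = maxit, rel_tol = rel_tol,
       inner_tol = inner_tol, inner_maxit = inner_maxit, se = se)
}

## ---- exposed likelihood operations ---------------------------------------

#' Laplace-approximated negative log marginal likelihood
#'
#' Evaluates the marginal likelihood of the counts with the latent
#' structured field and nugget integrated out by the Laplace approximation
#' at their joint conditional mode, for a fixed parameter set.
#'
#' @param params an [lgcp_params()]
#' @param data a [haul_table()]
#' @param grid a [build_lattice()] lattice
#' @param spec an [lgcp_spec()]
#' @return scalar negative log likelihood
#' @export
nll_laplace <- function(params, data, grid, spec) {
  obj <- make_obj(data, grid, spec, params)
  v <- obj$fn(obj$par)
  if (!is.finite(v)) stop("non-finite likelihood (inner Newton diverged?)")
  as.numeric(v)
}

#' Conditional mode of the latent fields
#'
#' The joint posterior mode of the standardized structured field `xi`
#' (classes x cells) and nugget `eps` given the counts, at fixed
#' parameters, together with inner-optimisation diagnostics.
#'
#' @inheritParams nll_laplace
#' @return list with `xi` (K x M matrix), `eps` (vector), `hessian` (sparse
#'   curvature of the joint negative log density at the mode, ordered as
#'   `c(vec(xi), eps)`), `grad_norm` (gradient norm at the mode) and
#'   `hessian_pd` (positive definiteness of the curvature)
#' @export
latent_mode <- function(params, data, grid, spec) {
  obj <- make_obj(data, grid, spec, params)
  obj$fn(obj$par)
  lp <- obj$env$last.par.best
  pl <- obj$env$parList(par = lp)
  g <- obj$env$f(lp, order = 1)
  r <- obj$env$random
  H <- obj$env$spHess(lp, random = TRUE)
  pd <- !inherits(try(Matrix::Cholesky(H), silent = TRUE), "try-error")
  K <- spec_k(spec)
  list(
    xi = matrix(pl$xi, nrow = K),
    eps = pl$eps,
    hessian = H,
    grad_norm = max(abs(g[r])),
    hessian_pd = pd
  )
}

#' Fit a size-structured LGCP model by maximum likelihood
#'
#' Minimizes the Laplace-approximated negative log marginal likelihood over
#' all model parameters (magnitudes, spatial range, size/joint correlation
#' parameters and per-class means) with a quasi-Newton optimiser using exact
#' AD gradients.  Magnitudes and scale parameters are optimised on the log
#' scale, the group correlation through `tanh`, and the unconstrained
#' correlations through hyperspherical angles / the cross-block `R`.
#'
#' @inheritParams nll_laplace
#' @param init optional [lgcp_params()] (or partial named list) of starting
#'   values; per-class means default to log mean counts
#' @param control an [lgcp_control()] list
#' @return object of class `lgcp_fit`: parameter estimates on the natural
#'   scale, standard errors, deviance (`2 *` minimized negative log
#'   likelihood), count of free covariance parameters, convergence
#'   diagnostics, and the fitted correlation factors
#' @export
lgcp_fit <- function(data, grid, spec, init = NULL,
                     control = lgcp_control()) {
  idx <- index_haul_table(data, spec)
  start <- default_init(spec, idx, init)
  obj <- make_obj(data, grid, spec, start,
                  profile_mu = control$profile_mu,
                  inner_tol = control$inner_tol,
                  inner_maxit = control$inner_maxit)
  bl <- par_bounds(names(obj$par))
  opt <- stats::nlminb(
    obj$par, obj$fn, obj$gr, lower = bl$lower, upper = bl$upper,
    control = list(iter.max = control$maxit, eval.max = 2 * control$maxit,
                   rel.tol = control$rel_tol)
  )
  conv <- list(code = opt$convergence, message = opt$message, pdHess = NA)
  if (opt$convergence != 0)
    warning("fit did not converge cleanly: ", opt$message)

  sdr <- NULL
  se <- NULL
  if (control$se) {
    sdr <- try(suppressWarnings(
      TMB::sdreport(obj, getReportCovariance = FALSE)), silent = TRUE)
    if (inherits(sdr, "try-error")) {
      sdr <- NULL
    } else {
      conv$pdHess <- sdr$pdHess
      sm <- TMB::summary.sdreport(sdr, "report")
      nm <- rownames(sm)
      nm <- stats::ave(nm, nm, FUN = function(v)
        if (length(v) > 1) paste0(v, seq_along(v)) else v)
      se <- stats::setNames(sm[, "Std. Error"], nm)
      est_nat <- stats::setNames(sm[, "Estimate"], nm)
      attr(se, "estimate") <- est_nat
    }
  }
  se_fixed <- if (!is.null(sdr)) {
    nmf <- names(sdr$par.fixed)
    nmf <- stats::ave(nmf, nmf, FUN = function(v)
      if (length(v) > 1) paste0(v, seq_along(v)) else v)
    stats::setNames(sqrt(diag(sdr$cov.fixed)), nmf)
  }

  pl <- obj$env$parList(par = obj$env$last.par.best)
  rep <- obj$report(obj$env$last.par.best)
  est <- list(
    mu = as.numeric(pl$mu),
    sigma = exp(pl$log_sigma), sigma_eps = exp(pl$log_sigma_eps),
    delta = exp(pl$log_delta),
    a = exp(pl$log_a), b = exp(pl$log_b), c = exp(pl$log_c),
    L50 = if (spec$transform == "logistic") pl$L50,
    alpha = if (spec$transform == "logistic") exp(pl$log_alpha),
    rho = if (isTRUE(spec$cross_model == "separable")) tanh(pl$rho_t),
    R = if (isTRUE(spec$cross_model == "unconstrained"))
      matrix(pl$Rvec, n_classes(spec$axis)),
    theta = if (spec$size_model == "unconstrained") pl$theta
  )

  structure(
    list(spec = spec, estimates = est, se = se, se_fixed = se_fixed,
         nll = as.numeric(opt$objective),
         deviance = 2 * as.numeric(opt$objective),
         total_df = total_df(spec),
         convergence = conv, opt = opt,
         C = rep$C, S = rep$S,
         data = data, grid = grid, obj = obj, sdreport = sdr),
    class = "lgcp_fit"
  )
}

## data-driven default starting values
default_init <- function(spec, idx, init = NULL) {
  cpue <- tapply(idx$obs_count, idx$obs_class, mean)
  mu0 <- rep(0, idx$K)
  mu0[as.integer(names(cpue)) + 1L] <- log(as.numeric(cpue) + 0.05)
  base <- lgcp_params(spec, mu = mu0, sigma = 0.5, sigma_eps = 0.5,
                      delta = 1)
  if (is.null(init)) return(base)
  if (inherits(init, "lgcp_params")) init <- unclass(init)
  for (nm in names(init)) if (!is.null(init[[nm]])) base[[nm]] <- init[[nm]]
  lgcp_params(spec, mu = base$mu, sigma = base$sigma,
              sigma_eps = base$sigma_eps, delta = base$delta, a = base$a,
              b = base$b, c = base$c, L50 = base$L50, alpha = base$alpha,
              rho = base$rho, R = base$R, theta = base$theta)
}

#' @export
print.lgcp_fit <- function(x, ...) {
  cat("Size-structured LGCP fit,", x$spec$family, "\n")
  cat("  deviance:", format(x$deviance, nsmall = 2), "  total df:",
      x$total_df, "\n")
  cat("  sigma:", signif(x$estimates$sigma, 3),
      " sigma_eps:", signif(x$estimates$sigma_eps, 3),
      " delta:", signif(x$estimates$delta, 3), "\n")
  if (x$spec$size_model == "structured")
    cat("  a:", signif(x$estimates$a, 3), " b:", signif(x$estimates$b, 3),
        " c:", signif(x$estimates$c, 3), "\n")
  if (!is.null(x$estimates$rho)) cat("  rho:", signif(x$estimates$rho, 3), "\n")
  cat("  convergence code:", x$convergence$code,
      if (!is.na(x$convergence$pdHess))
        paste0("(pd Hessian: ", x$convergence$pdHess, ")"), "\n")
  invisible(x)
}

## natural parameter name -> name of the optimised (transformed) parameter
transformed_name <- function(nm) {
  out <- ifelse(startsWith(nm, "rho"), "rho_t", paste0("log_", nm))
  ifelse(nm %in% c("sigma", "sigma_eps", "delta"),
         paste0("log_", nm), out)
}

## natural-scale parameter vector (and SEs) for recovery summaries
fit_param_vector <- function(fit) {
  e <- fit$estimates
  v <- c(sigma = e$sigma, sigma_eps = e$sigma_eps, delta = e$delta)
  add <- function(v, x, nm)
    if (is.null(x)) v else c(v, stats::setNames(x, if (length(x) == 1) nm
                                                else paste0(nm, seq_along(x))))
  v <- add(v, e$a, "a"); v <- add(v, e$b, "b"); v <- add(v, e$c, "c")
  v <- add(v, e$rho, "rho")
  v
}
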