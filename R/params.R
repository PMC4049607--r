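`%||%` <- function(a, b) if (is.null(a)) b else a

## lengths of the oscillation parameter vectors implied by sharing flags
osc_lengths <- function(spec) {
  if (!spec$joint) return(c(a = 1L, b = 1L, c = 1L))
  n <- ifelse(c("a", "b", "c") %in% spec$share, 1L, 2L)
  names(n) <- c("a", "b", "c")
  n
}

## template index (0-based) into log_a/log_b/log_c for each group
osc_index <- function(spec) {
  n <- osc_lengths(spec)
  g2 <- function(len) if (len == 1L) c(0L, 0L) else c(0L, 1L)
  c(g2(n["a"]), g2(n["b"]), g2(n["c"]))
}

#' Model parameter set
#'
#' Collects the covariance parameters and nuisance means of a model spec,
#' used as simulation truth, fit initialisation or evaluation point.
#' Unspecified values get defaults of the magnitude typically estimated for
#' demersal trawl surveys (field magnitude below 1, nugget comparable,
#' moderate spatial range).
#'
#' @param spec an [lgcp_spec()]
#' @param mu mean log density per joint class (recycled; default 1)
#' @param sigma,sigma_eps magnitudes of the structured field and the nugget
#' @param delta positive GMRF range parameter
#' @param a,b,c oscillating-correlation parameters, per group where not
#'   shared (recycled to the required length)
#' @param L50,alpha logistic transform parameters (logistic scale only)
#' @param rho overall group correlation (separable joint models)
#' @param R cross-block matrix (unconstrained joint models), default 0
#' @param theta hyperspherical parameters (unconstrained size correlation),
#'   default 0 (identity correlation)
#' @return object of class `lgcp_params`
#' @export
lgcp_params <- function(spec, mu = NULL, sigma = 0.8, sigma_eps = 0.6,
                        delta = 1, a = NULL, b = NULL, c = NULL,
                        L50 = NULL, alpha = NULL, rho = 0, R = NULL,
                        theta = NULL) {
  stopifnot(inherits(spec, "lgcp_spec"))
  K <- spec_k(spec)
  n <- osc_lengths(spec)
  ## default decay scale matched to the transform: ~5 cm on the natural
  ## scale, ~0.3 on the log and logistic (unit-range) scales
  a_def <- switch(spec$transform, identity = 5, log = 0.3, logistic = 0.3)
  b_def <- switch(spec$transform, identity = 0.3, log = 2, logistic = 2)
  p <- list(
    mu = rep_len(mu %||% 1, K),
    sigma = sigma, sigma_eps = sigma_eps, delta = delta,
    a = rep_len(a %||% a_def, n["a"]),
    b = rep_len(b %||% b_def, n["b"]),
    c = rep_len(c %||% 0.5, n["c"]),
    L50 = L50, alpha = alpha, rho = rho,
    R = R, theta = theta
  )
  if (spec$transform == "logistic") {
    mid <- spec_class_sizes(spec)
    p$L50 <- L50 %||% stats::median(mid)
    p$alpha <- alpha %||% 0.3
  }
  if (spec$joint && spec$cross_model == "unconstrained") {
    kA <- n_classes(spec$axis); kB <- n_classes(spec$axis_b)
    p$R <- R %||% matrix(0, kA, kB)
    stopifnot(identical(dim(p$R), c(kA, kB)))
  }
  if (spec$size_model == "unconstrained") {
    k <- n_classes(spec$axis)
    p$theta <- rep_len(theta %||% 0, k * (k - 1) / 2)
  }
  if (p$sigma < 0 || p$sigma_eps < 0) stop("magnitudes must be >= 0")
  if (p$delta <= 0) stop("'delta' must be positive")
  if (abs(p$rho) > 1) stop("'rho' must lie in [-1, 1]")
  check_osc_params(p$a[1], p$b[1], p$c[1])
  structure(p, class = "lgcp_params", spec_family = spec$family)
}

## size transform object implied by spec + params
spec_transform <- function(spec, params) {
  size_transform(spec$transform, L50 = params$L50, alpha = params$alpha)
}

#' Latent log density at a haul
#'
#' The log of the Poisson mean for one haul and size class:
#' `eta = mu(class) + xi(class, cell of haul) + eps(haul, class)`.  Two
#' hauls in the same cell share the structured field value `xi` but carry
#' independent nugget values `eps` -- the nugget models the catch-process
#' noise of repeating a haul at a nearby position.
#'
#' @param params an [lgcp_params()]
#' @param latent a latent state as returned by [simulate_latent()] (fields
#'   `xi`, `eps`, `hauls`; already scaled by the magnitudes)
#' @param haul haul index into `latent$hauls`
#' @param class joint class index (group A classes first)
#' @return scalar log density `eta`; the Poisson mean is `exp(eta)`
#' @export
log_density <- function(params, latent, haul, class) {
  if (haul < 1 || haul > nrow(latent$hauls)) stop("unknown haul: ", haul)
  K <- nrow(latent$xi)
  if (class < 1 || class > K) stop("unknown size class: ", class)
  cell <- latent$hauls$cell[haul]
  eps_h <- latent$eps[[haul]]
  ## year-blocked hauls store only their own block's nugget
  local <- class
  if (length(eps_h) < K) {
    kA <- K - length(eps_h)  # only two equal blocks supported
    local <- if (latent$hauls$block[haul] == 1L) class else class - kA
    if (local < 1 || local > length(eps_h))
      stop("class ", class, " is not observed by haul ", haul)
  }
  params$mu[class] + latent$xi[class, cell] + eps_h[local]
}

#' Joint correlation matrix implied by a spec and parameters
#'
#' Pure-R construction of the (species/year, size) correlation factor:
#' structured oscillating correlation within groups, combined across groups
#' by the independence, separable or unconstrained cross-block model.
#'
#' @param spec an [lgcp_spec()]
#' @param params an [lgcp_params()]
#' @return correlation matrix over all joint classes
#' @export
spec_joint_corr <- function(spec, params) {
  tr <- spec_transform(spec, params)
  rep2 <- function(v) rep_len(v, 2)
  if (spec$size_model == "unconstrained")
    return(unconstrained_corr(params$theta, n_classes(spec$axis)))
  if (!spec$joint)
    return(size_corr_matrix(spec$axis, tr, params$a, params$b, params$c))
  a <- rep2(params$a); b <- rep2(params$b); c <- rep2(params$c)
  switch(spec$cross_model,
    independent = {
      SA <- size_corr_matrix(spec$axis, tr, a[1], b[1], c[1])
      SB <- size_corr_matrix(spec$axis_b, tr, a[2], b[2], c[2])
      kA <- nrow(SA); kB <- nrow(SB)
      rbind(cbind(SA, matrix(0, kA, kB)), cbind(matrix(0, kB, kA), SB))
    },
    separable = separable_cross(spec$axis, spec$axis_b, params$rho, tr,
                                a[1], b[1], c[1]),
    unconstrained = {
      SA <- size_corr_matrix(spec$axis, tr, a[1], b[1], c[1])
      SB <- size_corr_matrix(spec$axis_b, tr, a[2], b[2], c[2])
      cross_block(SA, SB, params$R)
    })
}
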