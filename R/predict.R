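## conditional mode of xi given (possibly reduced) data at fitted parameters
conditional_xi <- function(fit, data) {
  K <- spec_k(fit$spec)
  M <- n_cells(fit$grid)
  if (is.null(data) || nrow(data) == 0L)
    return(matrix(0, K, M))          # prior mean of the zero-mean field
  obj <- make_obj(data, fit$grid, fit$spec, fit_params(fit))
  obj$fn(obj$par)
  matrix(obj$env$parList(par = obj$env$last.par.best)$xi, nrow = K)
}

## estimates repackaged as an lgcp_params object
fit_params <- function(fit) {
  e <- fit$estimates
  lgcp_params(fit$spec, mu = e$mu, sigma = e$sigma, sigma_eps = e$sigma_eps,
              delta = e$delta, a = e$a, b = e$b, c = e$c, L50 = e$L50,
              alpha = e$alpha, rho = e$rho %||% 0, R = e$R, theta = e$theta)
}

## joint-class indices for a target group / size range
target_classes <- function(spec, group = NULL, sizes = NULL) {
  gidx <- spec_group_of_class(spec)
  lower <- c(spec$axis$lower, if (spec$joint) spec$axis_b$lower)
  sel <- rep(TRUE, length(gidx))
  if (spec$joint) {
    if (is.null(group)) stop("joint models need a target 'group'")
    g <- match(as.character(group), spec$groups)
    if (is.na(g)) stop("unknown group label: ", group)
    sel <- gidx == g
  }
  if (!is.null(sizes)) {
    if (length(sizes) != 2L) stop("'sizes' must be c(lower, upper) in cm")
    sel <- sel & lower >= sizes[1] & lower <= sizes[2]
  }
  if (!any(sel)) stop("no size classes match the target")
  which(sel)
}

new_surface <- function(fit, logval, group, sizes) {
  g <- fit$grid
  structure(
    data.frame(cell = g$cell_ids, row = g$coords[, "row"],
               col = g$coords[, "col"], cell_centres(g),
               value = exp(logval)),
    class = c("lgcp_surface", "data.frame"),
    group = group, sizes = sizes, family = fit$spec$family
  )
}

#' Predict a relative abundance surface
#'
#' The conditional mode of the latent log-density field given the counts,
#' exponentiated per water cell: `exp(mu_hat + sigma_hat * xi_hat)`,
#' averaged on the log scale over the requested size classes.  Values are
#' relative abundances (an empirical-Bayes plug-in, with no lognormal mean
#' correction): the surface shape, not absolute numbers, is the estimand.
#' Cells far (in water-graph distance) from every haul shrink toward the
#' stationary surface `exp(mu_hat)`.
#'
#' @param fit an [lgcp_fit()]
#' @param data haul table to condition on (default: the fitted data)
#' @param group target group label (species or year; joint fits only)
#' @param sizes optional inclusive cm range `c(lower, upper)` of class
#'   lower bounds to average over (default: all classes of the group)
#' @return data frame of class `lgcp_surface` with cell coordinates and a
#'   non-negative relative abundance `value` per water cell
#' @export
predict_surface <- function(fit, data = NULL, group = NULL, sizes = NULL) {
  stopifnot(inherits(fit, "lgcp_fit"))
  if (is.null(data)) data <- fit$data
  cls <- target_classes(fit$spec, group, sizes)
  xi <- conditional_xi(fit, data)
  e <- fit$estimates
  logsurf <- e$mu[cls] + e$sigma * xi[cls, , drop = FALSE]
  logval <- colMeans(matrix(logsurf, nrow = length(cls)))
  new_surface(fit, logval, group, sizes)
}

#' Cross-prediction from indirect data
#'
#' Predicts the abundance surface of a target species (or year) from a
#' joint fit while conditioning the latent field only on the counts of the
#' *other* species (or the previous year).  Information flows through the
#' between-group correlation of the joint model: under independence
#' (`rho = 0` or a zero cross-block) the returned surface is flat at
#' `exp(mu_hat)`.
#'
#' @param fit a joint (`MS*` or `MY*`) [lgcp_fit()]
#' @param group target group label whose surface is predicted
#' @param aux_data haul table of the auxiliary group used for conditioning
#'   (default: the fitted data restricted to the non-target group)
#' @param sizes optional inclusive cm range of target class lower bounds
#' @return an `lgcp_surface` for the target group
#' @export
cross_predict <- function(fit, group, aux_data = NULL, sizes = NULL) {
  stopifnot(inherits(fit, "lgcp_fit"))
  spec <- fit$spec
  if (!spec$joint) stop("cross-prediction needs a joint (MS/MY) fit")
  g <- match(as.character(group), spec$groups)
  if (is.na(g)) stop("unknown group label: ", group)
  other <- spec$groups[3 - g]
  if (is.null(aux_data)) {
    col <- if (spec$role == "species") "species" else "year"
    df <- as.data.frame(fit$data)
    aux_data <- df[as.character(df[[col]]) == other, , drop = FALSE]
    if (nrow(aux_data) > 0L)
      aux_data <- haul_table(aux_data, width = attr(fit$data, "width"))
  }
  if (is.null(aux_data) || nrow(aux_data) == 0L) {
    warning("auxiliary data empty: returning the flat prior surface")
    aux_data <- NULL
  }
  cls <- target_classes(spec, group, sizes)
  xi <- conditional_xi(fit, aux_data)
  e <- fit$estimates
  logsurf <- e$mu[cls] + e$sigma * xi[cls, , drop = FALSE]
  logval <- colMeans(matrix(logsurf, nrow = length(cls)))
  new_surface(fit, logval, group, sizes)
}

#' @export
print.lgcp_surface <- function(x, ...) {
  cat("Relative abundance surface over", nrow(x), "water cells")
  if (!is.null(attr(x, "group"))) cat(" (group", attr(x, "group"), ")")
  if (!is.null(attr(x, "sizes")))
    cat(", sizes", paste(attr(x, "sizes"), collapse = "-"), "cm")
  cat("\n  value range:", paste(signif(range(x$value), 4), collapse = " - "),
      "\n")
  invisible(x)
}

#' Plot a relative abundance surface
#'
#' Renders the water lattice as a raster; land cells are blank.
#'
#' @param x an `lgcp_surface`
#' @param main title
#' @param ... passed to [graphics::image()]
#' @export
plot.lgcp_surface <- function(x, main = NULL, ...) {
  nr <- max(x$row); nc <- max(x$col)
  z <- matrix(NA_real_, nr, nc)
  z[cbind(x$row, x$col)] <- x$value
  graphics::image(
    x = seq_len(nc), y = seq_len(nr), z = t(z)[, nr:1, drop = FALSE],
    col = grDevices::hcl.colors(64, "viridis"), xlab = "column",
    ylab = "row", main = main %||% "relative abundance", ...
  )
  invisible(x)
}
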