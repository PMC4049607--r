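#' Model family specification
#'
#' Declares which member of the model hierarchy to fit and how the data map
#' onto it.  Single-group families model one species in one period:
#' \describe{
#'   \item{SS1}{unconstrained positive definite size correlation}
#'   \item{SS2}{structured oscillating correlation on the natural cm scale}
#'   \item{SS3}{structured, on the log size scale}
#'   \item{SS4}{structured, on the logistic size scale (adds `L50`, `alpha`)}
#' }
#' Joint families couple two species in one period (`MS*`) or one species in
#' two years (`MY*`) -- species and year simply switch roles:
#' \describe{
#'   \item{MS1/MY1}{unconstrained cross-block `R`, group-specific `a, b, c`}
#'   \item{MS2/MY2}{unconstrained cross-block, common `a, b, c`}
#'   \item{MS3/MY3}{separable: common size correlation times an overall
#'     group correlation `rho`}
#'   \item{MS4/MY4}{independence (`rho = 0`)}
#' }
#' The hierarchy used for nested likelihood-ratio testing is
#' `SS2/SS3/SS4 < SS1` and `*4 < *3 < *2 < *1` for the joint families.
#'
#' @param family model label, e.g. `"SS3"` or `"MS3"`
#' @param axis [size_axis()] of group A (and of group B unless `axis_b`)
#' @param axis_b optional [size_axis()] for group B (joint families)
#' @param groups character vector of group labels matched against the
#'   `species` column (MS) or `year` column (MY) of the haul table; length 1
#'   for single-group families, length 2 for joint ones
#' @param transform size transform kind; defaults to the family's canonical
#'   scale (`SS2` natural, `SS3`/joint families log, `SS4` logistic)
#' @param share which of `a`, `b`, `c` are common to the two groups in joint
#'   families (default all three for MS2-MS4/MY2-MY4, none for MS1/MY1)
#' @param kappa fixed GMRF coupling parameter (default 1; only `delta/kappa`
#'   is identifiable after standardization)
#' @return object of class `lgcp_spec`
#' @export
lgcp_spec <- function(family = c("SS1", "SS2", "SS3", "SS4",
                                 "MS1", "MS2", "MS3", "MS4",
                                 "MY1", "MY2", "MY3", "MY4"),
                      axis, axis_b = NULL, groups = NULL,
                      transform = NULL, share = NULL, kappa = 1) {
  family <- match.arg(family)
  stopifnot(inherits(axis, "size_axis"))
  type <- substr(family, 1, 2)
  level <- as.integer(substr(family, 3, 3))
  joint <- type != "SS"
  role <- switch(type, SS = "single", MS = "species", MY = "year")

  if (joint) {
    if (is.null(axis_b)) axis_b <- axis
    if (is.null(groups) || length(groups) != 2L)
      stop("joint families need two group labels (species or years)")
    groups <- as.character(groups)
    if (anyDuplicated(groups)) stop("group labels must differ")
  } else {
    axis_b <- NULL
    if (length(groups) > 1L)
      stop("single-group families take at most one group label")
    groups <- if (length(groups)) as.character(groups)
  }

  size_model <- if (!joint && level == 1L) "unconstrained" else "structured"
  cross_model <- if (!joint) NULL else
    switch(level, "unconstrained", "unconstrained", "separable", "independent")

  if (is.null(transform))
    transform <- if (!joint)
      switch(level, "identity", "identity", "log", "logistic") else "log"
  transform <- match.arg(transform, c("identity", "log", "logistic"))

  if (is.null(share))
    share <- if (joint && level >= 2L) c("a", "b", "c") else character(0)
  share <- intersect(share, c("a", "b", "c"))
  if (joint && cross_model %in% c("separable", "independent") &&
      length(share) != 3L)
    stop("separable and independence models require a common size ",
         "correlation (share = c('a','b','c'))")

  structure(
    list(family = family, role = role, joint = joint,
         size_model = size_model, cross_model = cross_model,
         transform = transform, share = share,
         axis = axis, axis_b = axis_b, groups = groups, kappa = kappa),
    class = "lgcp_spec"
  )
}

#' @export
print.lgcp_spec <- function(x, ...) {
  cat("LGCP model spec", x$family, "(", x$role, ")\n")
  cat("  size model:", x$size_model, "on", x$transform, "scale\n")
  if (x$joint) {
    cat("  cross model:", x$cross_model,
        if (length(x$share)) paste0("(common ", paste(x$share, collapse = ","), ")"),
        "\n")
    cat("  groups:", paste(x$groups, collapse = " vs "), "\n")
  }
  cat(" ", n_classes(x$axis),
      if (x$joint) paste("+", n_classes(x$axis_b)), "size classes\n")
  invisible(x)
}

## joint class bookkeeping: classes stacked [group A, group B]
spec_k <- function(spec) {
  n_classes(spec$axis) + if (spec$joint) n_classes(spec$axis_b) else 0L
}

spec_group_of_class <- function(spec) {
  kA <- n_classes(spec$axis)
  if (!spec$joint) rep.int(1L, kA)
  else rep.int(c(1L, 2L), c(kA, n_classes(spec$axis_b)))
}

spec_class_sizes <- function(spec) {
  c(spec$axis$midpoints, if (spec$joint) spec$axis_b$midpoints)
}

#' Count of free covariance parameters of a model spec
#'
#' The degrees of freedom used in likelihood-ratio comparisons: all free
#' covariance-structure parameters (size/joint correlation parameters plus
#' the magnitudes `sigma`, `sigma_eps` and the spatial `delta`), excluding
#' the per-class nuisance means `mu`.
#'
#' @param spec an [lgcp_spec()]
#' @return integer
#' @examples
#' ax45 <- size_axis(seq_len(45))
#' total_df(lgcp_spec("SS1", ax45))  # 45*44/2 + 3 = 993
#' total_df(lgcp_spec("SS2", ax45))  # 6
#' total_df(lgcp_spec("SS4", ax45))  # 8
#' @export
total_df <- function(spec) {
  stopifnot(inherits(spec, "lgcp_spec"))
  base <- 3L                                  # sigma, sigma_eps, delta
  if (!spec$joint) {
    k <- n_classes(spec$axis)
    corr <- if (spec$size_model == "unconstrained") (k * (k - 1L)) %/% 2L
            else 3L + if (spec$transform == "logistic") 2L else 0L
    return(base + corr)
  }
  n_osc <- sum(ifelse(c("a", "b", "c") %in% spec$share, 1L, 2L))
  n_tr <- if (spec$transform == "logistic") 2L else 0L
  cross <- switch(spec$cross_model,
    unconstrained = n_classes(spec$axis) * n_classes(spec$axis_b),
    separable = 1L,
    independent = 0L)
  base + n_osc + n_tr + cross
}

## hierarchy rank: smaller = more general; nested test runs general -> restricted
spec_rank <- function(family) as.integer(substr(family, 3, 3))

spec_type <- function(family) substr(family, 1, 2)

#' Is one model family nested in another?
#'
#' `SS2`, `SS3`, `SS4` are sub-models of `SS1`; within `MS*` and `MY*` each
#' higher-numbered member is nested in every lower-numbered one.
#'
#' @param sub,full family labels
#' @return logical
#' @export
is_nested <- function(sub, full) {
  if (spec_type(sub) != spec_type(full)) return(FALSE)
  if (spec_type(sub) == "SS")
    return(spec_rank(full) == 1L && spec_rank(sub) > 1L)
  spec_rank(sub) > spec_rank(full)
}
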