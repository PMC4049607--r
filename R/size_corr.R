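#' Size-class axis
#'
#' A contiguous axis of length classes (1-cm classes in raw survey data;
#' optionally re-binned to wider groups).  Distances between classes are
#' always computed between class midpoints.
#'
#' @param lower integer-ish vector of lower class bounds in cm, strictly
#'   increasing and equally spaced by `width`
#' @param width bin width in cm (default 1)
#' @return object of class `size_axis` with `lower`, `width`, `midpoints`
#' @examples
#' size_axis(10:19)            # 10 one-cm classes, midpoints 10.5..19.5
#' @export
size_axis <- function(lower, width = 1) {
  if (length(lower) < 1L) stop("empty size axis")
  if (any(diff(lower) <= 0)) stop("'lower' must be strictly increasing")
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("'width' must be a single positive number")
  structure(
    list(lower = as.numeric(lower), width = width,
         midpoints = as.numeric(lower) + width / 2),
    class = "size_axis"
  )
}

#' @export
print.size_axis <- function(x, ...) {
  cat(length(x$lower), "size classes of", x$width, "cm, from", min(x$lower),
      "to", max(x$lower) + x$width, "cm\n")
  invisible(x)
}

n_classes <- function(axis) length(axis$lower)

#' Size transforms
#'
#' A strictly increasing map of the cm length axis, applied before size
#' distances enter the correlation function.  `identity` uses raw cm;
#' `log` makes correlation depend on size ratios rather than differences;
#' `logistic`, `t(s) = 1/(1 + exp(-alpha (s - L50)))`, concentrates
#' resolution around `L50`, the length of fastest change in spatial
#' distribution, with `alpha` the rate of that change.
#'
#' @param kind one of `"identity"`, `"log"`, `"logistic"`
#' @param L50 centre of the logistic transform (cm); required for `logistic`
#' @param alpha positive rate of the logistic transform (1/cm)
#' @return object of class `size_transform`
#' @export
size_transform <- function(kind = c("identity", "log", "logistic"),
                           L50 = NULL, alpha = NULL) {
  kind <- match.arg(kind)
  if (kind == "logistic") {
    if (is.null(L50) || is.null(alpha))
      stop("logistic transform requires 'L50' and 'alpha'")
    if (alpha <= 0) stop("'alpha' must be positive")
  }
  structure(list(kind = kind, L50 = L50, alpha = alpha),
            class = "size_transform")
}

#' Apply a size transform to class midpoints
#'
#' @param axis a [size_axis()]
#' @param transform a [size_transform()]
#' @return numeric vector of transformed midpoints (strictly increasing)
#' @export
transform_sizes <- function(axis, transform = size_transform("identity")) {
  stopifnot(inherits(axis, "size_axis"), inherits(transform, "size_transform"))
  s <- axis$midpoints
  switch(transform$kind,
    identity = s,
    log = {
      if (any(s <= 0)) stop("log transform requires positive sizes")
      log(s)
    },
    logistic = 1 / (1 + exp(-transform$alpha * (s - transform$L50)))
  )
}

check_osc_params <- function(a, b, c) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0)
    stop("'b' must be a single non-negative number")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0)
    stop("'c' must be a single non-negative number")
}

#' Oscillating size-correlation function
#'
#' `rho(d) = exp(-d/a) * (cos(b d) + c) / (1 + c)` for a distance `d >= 0`
#' on the (transformed) size scale.  `a` sets the decay scale, `b` the
#' angular frequency of the oscillation and `c` its minimal amplitude: with
#' `b = 0` the function is a pure exponential decay, with `b > 0` and small
#' `c` the correlation can become negative -- the signature of small and
#' large fish sharing grounds that intermediate sizes avoid.  Each summand
#' `exp(-d/a) cos(b d)` and `exp(-d/a) c` is a valid one-dimensional
#' autocorrelation (Bochner), so the normalized sum is positive definite.
#'
#' @param d non-negative distance(s) on the transformed size scale
#' @param a positive decay scale
#' @param b non-negative angular frequency
#' @param c non-negative oscillation offset
#' @return correlation value(s); equals 1 at `d = 0`
#' @export
oscillating_correlation <- function(d, a, b = 0, c = 0) {
  check_osc_params(a, b, c)
  if (any(d < 0)) stop("'d' must be non-negative")
  exp(-d / a) * (cos(b * d) + c) / (1 + c)
}

#' Structured size-correlation matrix
#'
#' Entry (i, j) is [oscillating_correlation()] evaluated at the distance
#' between transformed midpoints of classes i and j.
#'
#' @inheritParams transform_sizes
#' @inheritParams oscillating_correlation
#' @return symmetric unit-diagonal k x k matrix
#' @export
size_corr_matrix <- function(axis, transform = size_transform("identity"),
                             a, b = 0, c = 0) {
  t <- transform_sizes(axis, transform)
  D <- abs(outer(t, t, "-"))
  M <- oscillating_correlation(D, a, b, c)
  diag(M) <- 1
  dimnames(M) <- NULL
  M
}

#' Unconstrained positive definite correlation matrix
#'
#' Bijective map from `k(k-1)/2` unconstrained reals to the open set of
#' k x k positive definite correlation matrices, via hyperspherical angles
#' of a unit-row lower-triangular Cholesky factor: each real `theta` is
#' mapped to an angle `phi = pi / (1 + exp(-theta))` in `(0, pi)`; row i of
#' the factor is the point on the unit sphere with those angles.
#' `theta = 0` (all angles `pi/2`) gives the identity matrix.
#'
#' @param theta numeric vector of length `k(k-1)/2` (row-wise: one angle for
#'   row 2, two for row 3, ...)
#' @param k number of classes
#' @return k x k correlation matrix, positive definite for every finite theta
#' @seealso [corr_to_theta()] for the inverse map
#' @export
unconstrained_corr <- function(theta, k) {
  if (k < 1L) stop("'k' must be >= 1")
  if (length(theta) != k * (k - 1) / 2)
    stop("'theta' must have length k(k-1)/2 = ", k * (k - 1) / 2)
  L <- diag(k)
  pos <- 0L
  for (i in seq_len(k)[-1]) {
    ang <- pi / (1 + exp(-theta[pos + seq_len(i - 1L)]))
    pos <- pos + i - 1L
    ## hyperspherical coordinates: L[i,j] = cos(ang_j) * prod_{l<j} sin(ang_l)
    sp <- 1
    for (j in seq_len(i - 1L)) {
      L[i, j] <- cos(ang[j]) * sp
      sp <- sp * sin(ang[j])
    }
    L[i, i] <- sp
  }
  C <- tcrossprod(L)
  diag(C) <- 1
  C
}

#' Recover hyperspherical parameters from a correlation matrix
#'
#' Inverse of [unconstrained_corr()]: computes the unit-row Cholesky factor
#' of `C`, reads off its angles and maps them back to unconstrained reals.
#'
#' @param C positive definite correlation matrix
#' @return numeric vector of length `k(k-1)/2`
#' @export
corr_to_theta <- function(C) {
  k <- nrow(C)
  L <- t(chol(C))                      # lower triangular, positive diagonal
  theta <- numeric(k * (k - 1) / 2)
  pos <- 0L
  for (i in seq_len(k)[-1]) {
    sp <- 1
    for (j in seq_len(i - 1L)) {
      x <- L[i, j] / sp
      x <- min(max(x, -1 + 1e-15), 1 - 1e-15)
      ang <- acos(x)
      theta[pos + j] <- log(ang / (pi - ang))
      sp <- sp * sin(ang)
    }
    pos <- pos + i - 1L
  }
  theta
}
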