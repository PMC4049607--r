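#' Positive definite cross-block extension of two correlation matrices
#'
#' Builds the joint (species, size) -- or (year, size) -- correlation
#' \deqn{\left[\begin{array}{cc} \Sigma_A & \Phi \\ \Phi' & \Sigma_B
#' \end{array}\right]}
#' with cross block `Phi = SigmaA^{1/2} R (I + R'R)^{-1/2} SigmaB^{1/2}`.
#' For any real `R` the contraction `R (I + R'R)^{-1/2}` has singular values
#' below one, so the joint matrix is positive definite and its diagonal
#' blocks equal `SigmaA` and `SigmaB` exactly: the within-group marginals
#' chosen in a single-group analysis are preserved while the between-group
#' correlation is free.  `R = 0` gives the block-diagonal (independence)
#' case.
#'
#' @param SigmaA,SigmaB positive definite correlation matrices (unit diag)
#' @param R any real matrix of dimension `nrow(SigmaA) x nrow(SigmaB)`
#' @return joint correlation matrix of dimension `kA + kB`
#' @export
cross_block <- function(SigmaA, SigmaB, R) {
  kA <- nrow(SigmaA); kB <- nrow(SigmaB)
  if (!is.matrix(R) || nrow(R) != kA || ncol(R) != kB)
    stop("'R' must be a ", kA, " x ", kB, " matrix")
  V <- R %*% sym_inv_sqrt(diag(kB) + crossprod(R))
  Phi <- sym_sqrt(SigmaA) %*% V %*% sym_sqrt(SigmaB)
  rbind(cbind(SigmaA, Phi), cbind(t(Phi), SigmaB))
}

## symmetric PD square root / inverse square root via eigendecomposition
sym_sqrt <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

sym_inv_sqrt <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  e$vectors %*% (1 / sqrt(e$values) * t(e$vectors))
}

#' Separable (species or year) x size joint correlation
#'
#' A common oscillating correlation function on a shared transformed size
#' scale applies within and between the two groups; entries between groups
#' are additionally multiplied by the overall group correlation `rho`.
#' Entry for class `u` of group A and class `v` of group B is
#' `rho * rho_size(|t(s_u) - t(s_v)|)`; within-group entries use factor 1.
#' The construction is positive (semi-)definite for `|rho| <= 1` and
#' block-diagonal (group independence) at `rho = 0`.
#'
#' @param axisA,axisB [size_axis()] of the two groups
#' @param rho overall between-group correlation in `[-1, 1]`
#' @param transform shared [size_transform()]
#' @param a,b,c shared oscillating-correlation parameters
#' @return joint correlation matrix of dimension `kA + kB`
#' @export
separable_cross <- function(axisA, axisB, rho,
                            transform = size_transform("identity"),
                            a, b = 0, c = 0) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) > 1)
    stop("'rho' must be a single number in [-1, 1]")
  tA <- transform_sizes(axisA, transform)
  tB <- transform_sizes(axisB, transform)
  tt <- c(tA, tB)
  D <- abs(outer(tt, tt, "-"))
  M <- oscillating_correlation(D, a, b, c)
  kA <- length(tA); kB <- length(tB)
  fac <- rbind(cbind(matrix(1, kA, kA), matrix(rho, kA, kB)),
               cbind(matrix(rho, kB, kA), matrix(1, kB, kB)))
  M <- M * fac
  diag(M) <- 1
  M
}

#' Materialize the full space x (species, size) covariance
#'
#' Dense Kronecker-product covariance `sigma^2 * (S_space \%x\% C_joint)`
#' for small instances; entry for ((cell1, class u), (cell2, class v)) is
#' `sigma^2 * S[cell1, cell2] * C[u, v]`.  Intended for checks and tiny
#' problems; fitting never forms this matrix.
#'
#' @param spatial spatial correlation matrix over `m` cells
#' @param joint joint (species, size) correlation over `k` classes
#' @param sigma magnitude of the structured field
#' @param cap maximum allowed dimension `m * k` (default 2000)
#' @return dense covariance matrix of dimension `m * k`, ordered cell-major
#'   (class index varies fastest)
#' @export
materialize_joint <- function(spatial, joint, sigma = 1, cap = 2000) {
  m <- nrow(spatial); k <- nrow(joint)
  if (m * k > cap)
    stop("dimension ", m * k, " exceeds cap ", cap,
         "; evaluate through the factored (Kronecker) form instead")
  sigma^2 * kronecker(as.matrix(spatial), as.matrix(joint))
}
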