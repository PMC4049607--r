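#' Build a water lattice from a raster mask
#'
#' Constructs the spatial domain of the model: a regular lattice of water
#' cells with rook (4-way) adjacency restricted to water.  The lattice is the
#' index set of the Gaussian Markov random field used for the spatial part of
#' the covariance, so correlation between two cells can only travel through
#' chains of water neighbours -- land acts as a barrier.
#'
#' @param mask logical or 0/1 matrix; `TRUE`/1 marks water.  Rows are lattice
#'   rows, columns lattice columns.  May also be a path to a plain-text 0/1
#'   raster readable by [read_mask()].
#' @param cell_size cell side length in km (default 20, a typical survey
#'   analysis resolution).
#' @return an object of class `lattice_grid` with components
#'   \describe{
#'     \item{cell_ids}{integer ids `1..n` in row-major order over water cells}
#'     \item{coords}{integer matrix (n x 2) of (row, col) per cell}
#'     \item{cell_size}{side length in km}
#'     \item{adjacency}{list of integer vectors, water neighbours per cell}
#'     \item{n_neighbours}{integer vector, `lengths(adjacency)`}
#'     \item{dim}{dimensions of the input mask}
#'   }
#' @examples
#' g <- build_lattice(matrix(TRUE, 3, 3))
#' g$n_neighbours  # centre cell has 4, corners 2
#' @export
build_lattice <- function(mask, cell_size = 20) {
  if (is.character(mask)) mask <- read_mask(mask)
  if (is.data.frame(mask)) mask <- as.matrix(mask)
  if (!is.matrix(mask)) stop("'mask' must be a matrix (or a path to one)")
  mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) stop("no water cells")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a single positive number")

  nr <- nrow(mask); nc <- ncol(mask)
  ## row-major ordering of water cells
  idx <- which(t(mask))                      # t() gives row-major scan
  col <- (idx - 1L) %% nc + 1L
  row <- (idx - 1L) %/% nc + 1L
  n <- length(idx)
  ## map (row, col) -> cell id
  id_of <- matrix(NA_integer_, nr, nc)
  id_of[cbind(row, col)] <- seq_len(n)

  adjacency <- vector("list", n)
  for (i in seq_len(n)) {
    r <- row[i]; cc <- col[i]
    nb <- c(
      if (r > 1L)  id_of[r - 1L, cc],
      if (r < nr)  id_of[r + 1L, cc],
      if (cc > 1L) id_of[r, cc - 1L],
      if (cc < nc) id_of[r, cc + 1L]
    )
    adjacency[[i]] <- as.integer(sort(nb[!is.na(nb)]))
  }

  structure(
    list(
      cell_ids     = seq_len(n),
      coords       = cbind(row = row, col = col),
      cell_size    = cell_size,
      adjacency    = adjacency,
      n_neighbours = lengths(adjacency),
      dim          = c(nr, nc)
    ),
    class = "lattice_grid"
  )
}

#' @export
print.lattice_grid <- function(x, ...) {
  cat("Water lattice:", length(x$cell_ids), "cells on a",
      x$dim[1], "x", x$dim[2], "grid, cell size", x$cell_size, "km\n")
  cat("Neighbour counts:", paste(range(x$n_neighbours), collapse = "-"), "\n")
  invisible(x)
}

n_cells <- function(grid) length(grid$cell_ids)

#' Edge list of a lattice grid
#'
#' Each water-adjacent pair (i, j), i < j, once.
#' @param grid a `lattice_grid`
#' @return integer matrix with columns `i`, `j`
#' @export
lattice_edges <- function(grid) {
  stopifnot(inherits(grid, "lattice_grid"))
  i <- rep.int(grid$cell_ids, grid$n_neighbours)
  j <- unlist(grid$adjacency, use.names = FALSE)
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

#' Cell centre coordinates in km
#'
#' Centres at `(col - 0.5, row - 0.5) * cell_size`; `x` runs along columns and
#' `y` along rows.
#' @param grid a `lattice_grid`
#' @return numeric matrix with columns `x`, `y`
#' @export
cell_centres <- function(grid) {
  stopifnot(inherits(grid, "lattice_grid"))
  cbind(x = (grid$coords[, "col"] - 0.5) * grid$cell_size,
        y = (grid$coords[, "row"] - 0.5) * grid$cell_size)
}

#' Assign points to containing lattice cells
#'
#' @param grid a `lattice_grid`
#' @param x,y positions in km (same origin as the mask: cell (1,1) spans
#'   `[0, cell_size)` in both axes)
#' @return integer vector of cell ids; error if any point falls on land or
#'   outside the lattice
#' @export
cells_from_xy <- function(grid, x, y) {
  stopifnot(inherits(grid, "lattice_grid"))
  col <- pmin(pmax(floor(x / grid$cell_size) + 1L, 1L), grid$dim[2])
  row <- pmin(pmax(floor(y / grid$cell_size) + 1L, 1L), grid$dim[1])
  key <- paste(grid$coords[, "row"], grid$coords[, "col"])
  id <- match(paste(row, col), key)
  if (anyNA(id)) stop("some positions fall on land or outside the lattice")
  id
}

check_spatial_params <- function(delta, kappa) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("'delta' must be a single positive number")
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be a single positive number")
}

#' GMRF precision matrix on the water lattice
#'
#' The sparse precision `Q` of the spatial random field:
#' `Q[i,i] = delta + kappa * n_i` with `n_i` the number of water neighbours of
#' cell `i`, and `Q[i,j] = -kappa` for water-adjacent pairs.  `Q` is symmetric
#' positive definite for any `delta > 0` (its smallest eigenvalue is at least
#' `delta`, since `Q - delta*I` is `kappa` times the graph Laplacian of the
#' water adjacency graph).
#'
#' After standardization of `Q^-1` to a correlation matrix only the ratio
#' `delta/kappa` is identifiable, so `kappa` is fixed at 1 by default and
#' `delta` is the single free spatial parameter: small `delta` gives
#' long-range correlation, large `delta` short-range.
#'
#' @param grid a `lattice_grid`
#' @param delta positive range-controlling parameter
#' @param kappa positive coupling parameter (fixed to 1 by default)
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`)
#' @export
precision_matrix <- function(grid, delta, kappa = 1) {
  stopifnot(inherits(grid, "lattice_grid"))
  check_spatial_params(delta, kappa)
  n <- n_cells(grid)
  ed <- lattice_edges(grid)
  ii <- c(seq_len(n), ed[, "i"])
  jj <- c(seq_len(n), ed[, "j"])
  xx <- c(delta + kappa * grid$n_neighbours, rep.int(-kappa, nrow(ed)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n), symmetric = TRUE)
}

#' Spatial correlation over water cells
#'
#' Inverts the GMRF precision and standardizes the result to unit diagonal.
#' Because the precision couples only water-adjacent cells, the resulting
#' correlation between two cells reflects all water paths connecting them:
#' it decreases with distance through the water and is reduced by land
#' barriers even when the Euclidean distance is short.
#'
#' @inheritParams precision_matrix
#' @return dense correlation matrix over cells (unit diagonal)
#' @export
spatial_correlation <- function(grid, delta, kappa = 1) {
  Q <- precision_matrix(grid, delta, kappa)
  V <- solve(Q)               # dense-ish inverse; grids are desk-scale
  V <- as.matrix(V)
  s <- sqrt(diag(V))
  C <- V / tcrossprod(s)
  diag(C) <- 1
  C
}
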