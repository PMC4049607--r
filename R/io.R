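#' Read a water mask from a plain-text raster
#'
#' Whitespace- or comma-separated 0/1 values, one lattice row per line
#' (1 = water).
#'
#' @param path file path
#' @return logical matrix
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), as.integer)
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged mask raster in ", path)
  m <- do.call(rbind, rows)
  if (!all(m %in% 0:1)) stop("mask must contain only 0 and 1")
  m == 1L
}

#' @rdname read_mask
#' @param mask logical matrix
#' @export
write_mask <- function(mask, path) {
  writeLines(apply(mask * 1L, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Rasterize a GeoJSON polygon into a water mask
#'
#' Reads the first (multi)polygon geometry of a GeoJSON file and marks a
#' lattice cell as water when its centre lies inside the polygon (even-odd
#' ray casting; holes are respected).  Coordinates are treated as planar
#' km, matching the lattice convention.
#'
#' @param path GeoJSON file with a `Polygon`/`MultiPolygon` geometry (bare,
#'   as a `Feature`, or inside a `FeatureCollection`)
#' @param cell_size lattice cell side length in km
#' @return logical matrix usable with [build_lattice()]; row 1 is the
#'   northern (maximum-y) edge
#' @export
read_geojson_mask <- function(path, cell_size = 20) {
  gj <- jsonlite::read_json(path)
  geom <- switch(gj$type %||% "",
    FeatureCollection = gj$features[[1]]$geometry,
    Feature = gj$geometry,
    Polygon = gj, MultiPolygon = gj,
    stop("unsupported GeoJSON type: ", gj$type))
  polys <- if (geom$type == "Polygon") list(geom$coordinates)
           else geom$coordinates
  rings <- lapply(unlist(polys, recursive = FALSE), function(r)
    do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]]))))
  allxy <- do.call(rbind, rings)
  nc <- ceiling(max(allxy[, 1]) / cell_size)
  nr <- ceiling(max(allxy[, 2]) / cell_size)
  in_ring <- function(x, y, R) {
    n <- nrow(R); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((R[i, 2] > y) != (R[j, 2] > y) &&
          x < (R[j, 1] - R[i, 1]) * (y - R[i, 2]) / (R[j, 2] - R[i, 2]) +
              R[i, 1])
        inside <- !inside
      j <- i
    }
    inside
  }
  mask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    x <- (cc - 0.5) * cell_size
    y <- (nr - r + 0.5) * cell_size      # row 1 at the top
    crossings <- sum(vapply(rings, function(R) in_ring(x, y, R), TRUE))
    mask[r, cc] <- crossings %% 2L == 1L
  }
  mask
}

#' Read / write a haul table as delimited text
#'
#' Tab-separated with columns `haul_id, x, y, year, quarter, species,
#' size_cm, count` (a `cell` column is accepted in place of `x`/`y`).
#'
#' @param path file path
#' @param grid optional lattice used to resolve `x`/`y` into cells
#' @param width size-class width in cm
#' @return a [haul_table()]
#' @export
read_haul_table <- function(path, grid = NULL, width = 1) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  haul_table(df, grid = grid, width = width)
}

#' @rdname read_haul_table
#' @param table a [haul_table()]
#' @export
write_haul_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

spec_to_list <- function(spec) {
  list(family = spec$family, transform = spec$transform, share = spec$share,
       groups = spec$groups, kappa = spec$kappa,
       axis = list(lower = spec$axis$lower, width = spec$axis$width),
       axis_b = if (!is.null(spec$axis_b))
         list(lower = spec$axis_b$lower, width = spec$axis_b$width))
}

list_to_spec <- function(x) {
  lgcp_spec(x$family,
            axis = size_axis(x$axis$lower, x$axis$width %||% 1),
            axis_b = if (!is.null(x$axis_b))
              size_axis(x$axis_b$lower, x$axis_b$width %||% 1),
            groups = if (length(x$groups)) unlist(x$groups),
            transform = x$transform,
            share = if (length(x$share)) unlist(x$share) else character(0),
            kappa = x$kappa %||% 1)
}

#' Serialize a fit to structured text (JSON)
#'
#' Stores the spec, natural-scale estimates, standard errors, deviance,
#' parameter count and convergence status -- everything needed for model
#' comparison and for re-evaluating the model, but not the data.
#'
#' @param fit an [lgcp_fit()]
#' @param path output file
#' @export
write_fit <- function(fit, path) {
  est <- fit$estimates
  est$R <- if (!is.null(est$R)) as.numeric(est$R)
  out <- list(
    spec = spec_to_list(fit$spec),
    estimates = est[!vapply(est, is.null, TRUE)],
    se = if (!is.null(fit$se)) as.list(fit$se),
    nll = fit$nll, deviance = fit$deviance, total_df = fit$total_df,
    convergence = fit$convergence
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized fit
#'
#' Returns a lightweight fit object (class `lgcp_fit_summary`) carrying the
#' spec, estimates, deviance and degrees of freedom; usable in
#' [lgcp_compare()] via its `model`/`total_df`/`deviance` fields.
#'
#' @param path file written by [write_fit()]
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spec <- list_to_spec(x$spec)
  structure(x, class = "lgcp_fit_summary")
}

#' Write a model comparison table as delimited text
#'
#' @param comparison an [lgcp_compare()] result
#' @param path output file
#' @export
write_comparison <- function(comparison, path) {
  utils::write.table(as.data.frame(comparison), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an abundance surface as delimited text
#'
#' Columns `cell, row, col, x, y, value`.
#'
#' @param surface an `lgcp_surface`
#' @param path output file
#' @export
write_surface <- function(surface, path) {
  utils::write.table(as.data.frame(surface), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
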