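#' Haul-level catch table
#'
#' One record per haul x species x size class with a non-negative integer
#' count.  Zero counts are retained explicitly (no-catch hauls carry
#' information), and every (haul, species, size class) combination covered
#' by the survey design must appear exactly once.
#'
#' @param df data frame with columns `haul_id`, `cell` (water-cell id) or
#'   `x`/`y` (km, resolved against `grid`), `year`, `quarter`, `species`,
#'   `size_cm` (lower class bound), `count`
#' @param grid optional [build_lattice()] grid used to resolve `x`/`y`
#'   positions into cells
#' @param width size-class bin width in cm (default 1)
#' @return data frame of class `haul_table` (attribute `width` records the
#'   bin width)
#' @export
haul_table <- function(df, grid = NULL, width = 1) {
  req <- c("haul_id", "year", "quarter", "species", "size_cm", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"cell" %in% names(df)) {
    if (!all(c("x", "y") %in% names(df)) || is.null(grid))
      stop("need a 'cell' column, or 'x'/'y' columns plus a grid")
    df$cell <- cells_from_xy(grid, df$x, df$y)
  }
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("counts must be non-negative integers")
  key <- interaction(df$haul_id, df$year, df$quarter, df$species, df$size_cm,
                     drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (haul, species, size class) records")
  ## a haul must sit in exactly one cell/period
  per_haul <- tapply(paste(df$cell, df$year, df$quarter), df$haul_id,
                     function(v) length(unique(v)))
  if (any(per_haul != 1L))
    stop("each haul_id must map to a single cell and period")
  df <- df[order(df$haul_id, df$species, df$size_cm), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("haul_table", "data.frame"), width = width)
}

#' @export
print.haul_table <- function(x, ...) {
  cat("Haul table:", length(unique(x$haul_id)), "hauls,",
      length(unique(x$species)), "species,",
      nrow(x), "records (", sum(x$count == 0), "zero counts ),",
      attr(x, "width"), "cm classes\n")
  NextMethod()
}

#' Re-bin counts to wider size classes
#'
#' Sums counts within consecutive groups of classes; total count per haul is
#' conserved.  Wider bins trade size resolution for fewer unconstrained
#' correlation parameters, which sharpens likelihood-ratio tests against the
#' unconstrained model.
#'
#' @param table a [haul_table()]
#' @param new_width new bin width in cm; must be an integer multiple of the
#'   current width
#' @return a `haul_table` with classes relabelled to the new lower bounds
#' @export
rebin_counts <- function(table, new_width) {
  stopifnot(inherits(table, "haul_table"))
  width <- attr(table, "width")
  if (new_width <= 0 || new_width %% width != 0)
    stop("'new_width' must be a positive integer multiple of the current ",
         "width (", width, ")")
  if (new_width == width) return(table)
  base <- min(table$size_cm)
  new_low <- base + ((table$size_cm - base) %/% new_width) * new_width
  agg <- stats::aggregate(
    count ~ haul_id + cell + year + quarter + species + size_cm,
    data = transform(as.data.frame(table), size_cm = new_low), FUN = sum)
  haul_table(agg, width = new_width)
}

## classes of the spec mapped onto the rows of a haul table; returns a list
## with integer indices used by the TMB backend (all 0-based)
index_haul_table <- function(table, spec) {
  stopifnot(inherits(table, "haul_table"), inherits(spec, "lgcp_spec"))
  df <- as.data.frame(table)
  group_col <- switch(spec$role, species = "species", year = "year",
                      single = NULL)
  if (is.null(group_col)) {
    if (!is.null(spec$groups)) df <- df[df$species == spec$groups, , drop = FALSE]
    if (length(unique(df$species)) > 1L || length(unique(df$year)) > 1L)
      stop("single-group spec but several species/years in data; ",
           "filter the table or set 'groups'")
    df$group <- 1L
  } else {
    df <- df[as.character(df[[group_col]]) %in% spec$groups, , drop = FALSE]
    if (nrow(df) == 0L) stop("no records match the spec's group labels")
    df$group <- match(as.character(df[[group_col]]), spec$groups)
  }

  axis_of <- function(g) if (g == 1L) spec$axis else spec$axis_b
  kA <- n_classes(spec$axis)
  cls_local <- integer(nrow(df))
  for (g in unique(df$group)) {
    ax <- axis_of(g)
    sel <- df$group == g
    m <- match(df$size_cm[sel], ax$lower)
    if (anyNA(m))
      stop("size classes in data not covered by the spec's axis (group ", g, ")")
    cls_local[sel] <- m
  }
  df$jclass <- cls_local + ifelse(df$group == 2L, kA, 0L)

  hauls <- unique(df[c("haul_id", "cell", "year", "quarter")])
  hauls <- hauls[order(hauls$haul_id), , drop = FALSE]
  df$haul_idx <- match(df$haul_id, hauls$haul_id)

  ## observation block per haul: which joint classes a haul observes.
  ## species-joint models observe both blocks in every haul; year-joint
  ## models observe only their own year's block.
  K <- spec_k(spec)
  if (spec$role == "year") {
    hgroup <- match(as.character(hauls$year), spec$groups)
    block_start <- c(0L, kA)
    block_len <- c(kA, K - kA)
    haul_block <- hgroup
  } else {
    block_start <- 0L
    block_len <- K
    haul_block <- rep.int(1L, nrow(hauls))
  }
  eps_off <- c(0L, cumsum(block_len[haul_block]))[seq_len(nrow(hauls))]
  local <- df$jclass - block_start[haul_block[df$haul_idx]]

  list(df = df, hauls = hauls, K = K,
       block_start = block_start, block_len = block_len,
       haul_block = haul_block, eps_off = eps_off,
       obs_haul = df$haul_idx - 1L,
       obs_class = df$jclass - 1L,
       obs_cell = hauls$cell[df$haul_idx] - 1L,
       obs_eps = eps_off[df$haul_idx] + local - 1L,
       obs_count = df$count)
}
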