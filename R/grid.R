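# Grid assembly: two 1-D binnings -> occupied rectangular cells with
# geometric areas, per-cell absolute Pearson coefficients and area weights.

# Degenerate per-cell correlation marker is NA_real_: a cell with a single
# point, or with zero variance in either coordinate, carries no linear
# signal that Pearson can quantify. A 2-point cell with distinct x and
# distinct y is exactly collinear, so it scores 1.
.abs_pearson <- function(xs, ys) {
  m <- length(xs)
  if (m < 2L) return(NA_real_)
  if (all(xs == xs[1L]) || all(ys == ys[1L])) return(NA_real_)
  if (m == 2L) return(1)
  r <- suppressWarnings(stats::cor(xs, ys))
  if (is.na(r)) return(NA_real_)
  min(abs(r), 1)
}

#' Absolute Pearson correlation with degenerate-cell conventions
#'
#' The per-cell association score used inside the MAC: `|r|` for three or
#' more points with variance in both coordinates; exactly 1 for two points
#' with distinct x and distinct y (two points are always collinear); and
#' `NA` (the degenerate marker) for a single point or zero variance in
#' either coordinate.
#'
#' @param xs,ys numeric vectors of equal length.
#' @return a number in \[0, 1\], or `NA_real_` for a degenerate cell.
#' @examples
#' abs_pearson(c(0, 1, 2), c(0, 2, 4)) # 1
#' abs_pearson(c(0, 1, 2), c(3, 3, 3)) # NA: no y-variance
#' @export
abs_pearson <- function(xs, ys) {
  if (length(xs) != length(ys)) {
    abort("`xs` and `ys` must have the same length.",
          class = "maxassoc_error_input")
  }
  if (length(xs) < 1L) {
    abort("`xs` and `ys` must contain at least one point.",
          class = "maxassoc_error_input")
  }
  .abs_pearson(as.double(xs), as.double(ys))
}

#' Normalize cell areas into grid weights
#'
#' Weights are the areas normalized to sum to one over the cells entering
#' the association coefficient. If every area is zero (a geometrically
#' degenerate grid) the weights fall back to uniform.
#'
#' @param areas non-negative numeric vector of cell areas.
#' @return numeric vector of weights summing to 1.
#' @examples
#' cell_weights(c(1, 3)) # 0.25 0.75
#' @export
cell_weights <- function(areas) {
  if (length(areas) < 1L) {
    abort("`areas` must contain at least one cell.",
          class = "maxassoc_error_input")
  }
  if (any(areas < 0)) {
    abort("cell areas must be non-negative.", class = "maxassoc_error_input")
  }
  tot <- sum(areas)
  if (tot > 0) areas / tot else rep(1 / length(areas), length(areas))
}

# Score one shape without materializing the cell tibble (hot path of mac()).
.ac_shape <- function(bx, by, xv, yv) {
  t_eff <- by$k_effective
  key <- (bx$assignments - 1L) * t_eff + by$assignments
  idx_by_cell <- split(seq_along(xv), key)
  keys <- as.integer(names(idx_by_cell))
  x_bin <- (keys - 1L) %/% t_eff + 1L
  y_bin <- (keys - 1L) %% t_eff + 1L
  area <- diff(bx$edges)[x_bin] * diff(by$edges)[y_bin]
  absp <- vapply(idx_by_cell, function(i) .abs_pearson(xv[i], yv[i]),
                 numeric(1), USE.NAMES = FALSE)
  valid <- !is.na(absp)
  nv <- sum(valid)
  ac <- if (nv == 0L) 0 else {
    # convex combination of values in [0, 1]; clamp floating-point drift
    min(1, max(0, sum(cell_weights(area[valid]) * absp[valid])))
  }
  list(ac = ac, n_cells = length(keys), n_valid = nv)
}

# Occupied-cell table for one (s, t) shape given the two binnings.
.cell_table <- function(bx, by, xv, yv) {
  t_eff <- by$k_effective
  key <- (bx$assignments - 1L) * t_eff + by$assignments
  idx_by_cell <- split(seq_along(xv), key)
  keys <- as.integer(names(idx_by_cell))
  x_bin <- (keys - 1L) %/% t_eff + 1L
  y_bin <- (keys - 1L) %% t_eff + 1L
  wx <- diff(bx$edges)[x_bin]
  wy <- diff(by$edges)[y_bin]
  area <- wx * wy
  absp <- vapply(
    idx_by_cell,
    function(i) .abs_pearson(xv[i], yv[i]),
    numeric(1)
  )
  valid <- !is.na(absp)
  weight <- rep(NA_real_, length(keys))
  if (any(valid)) weight[valid] <- cell_weights(area[valid])
  tibble::tibble(
    x_bin = x_bin,
    y_bin = y_bin,
    n_points = unname(lengths(idx_by_cell)),
    area = area,
    abs_pearson = absp,
    valid = valid,
    weight = weight,
    members = unname(idx_by_cell)
  )
}

# Association coefficient for one shape from its cell table:
# AC = sum_i w_i |p_i| over non-degenerate cells, 0 if none survive.
.ac_from_cells <- function(cells) {
  v <- cells$valid
  if (!any(v)) return(0)
  min(1, max(0, sum(cells$weight[v] * cells$abs_pearson[v])))
}

#' Build one s-by-t grid partition of a variable pair
#'
#' Bins each variable independently with [bin_kmeans()] and assembles the
#' occupied cells of the resulting rectangular grid. Each occupied cell
#' records its member points, geometric area (bin width times bin height),
#' absolute Pearson coefficient, and area weight among the non-degenerate
#' cells.
#'
#' @param data a data frame holding the two variables.
#' @param x,y column names (bare or quoted) of the two variables.
#' @param s,t requested bin counts for x and y.
#' @param seed integer seed; the binning of a variable into `k` bins uses a
#'   stream derived from `(seed, k)` only, matching [mac()].
#' @return an object of class `mac_grid`: a list with `shape`, the two
#'   `mac_binning`s, a `cells` tibble, and `n`.
#' @examples
#' d <- data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1))
#' g <- grid_partition(d, x, y, s = 2, t = 2, seed = 1)
#' g$cells$area # four cells of area 0.25
#' @export
grid_partition <- function(data, x = "x", y = "y", s, t, seed = 1L) {
  xv <- .as_numeric_column(data, {{ x }}, "x")
  yv <- .as_numeric_column(data, {{ y }}, "y")
  bx <- bin_kmeans(xv, s, seed = .subseed(seed, s))
  by <- bin_kmeans(yv, t, seed = .subseed(seed, t))
  cells <- .cell_table(bx, by, xv, yv)
  structure(
    list(
      shape = c(s = as.integer(s), t = as.integer(t)),
      x_binning = bx,
      y_binning = by,
      cells = cells,
      n = length(xv)
    ),
    class = "mac_grid"
  )
}

#' Per-cell statistics of one grid shape as a tibble
#'
#' Convenience wrapper around [grid_partition()] returning only the cell
#' table (one row per occupied cell, with areas, weights and absolute
#' Pearson coefficients).
#'
#' @inheritParams grid_partition
#' @return a tibble with columns `x_bin`, `y_bin`, `n_points`, `area`,
#'   `abs_pearson`, `valid`, `weight`, `members`.
#' @export
mac_cells <- function(data, x = "x", y = "y", s, t, seed = 1L) {
  grid_partition(data, {{ x }}, {{ y }}, s = s, t = t, seed = seed)$cells
}

#' @export
print.mac_grid <- function(x, ...) {
  cat(sprintf(
    "<mac_grid> %d x %d grid (effective %d x %d), %d occupied cell(s), n = %d\n",
    x$shape[["s"]], x$shape[["t"]],
    x$x_binning$k_effective, x$y_binning$k_effective,
    nrow(x$cells), x$n
  ))
  invisible(x)
}
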