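# Scripted experiment runners: the generality sweep over data sizes, the
# equitability sweep over noise levels, and vector comparison metrics.

.PAPER_SIZES <- c(10L, 20L, 40L, 80L, 100L, 200L, 400L, 800L, 1000L,
                  2000L, 4000L, 8000L, 10000L)

# default grid-budget exponents: finer grids for the functional types,
# coarser for the random type (where fine grids overfit small samples)
.generality_alpha <- function() {
  a <- c(rep(0.75, 9), 0.45)
  names(a) <- .RELATIONSHIPS
  a
}

# simpler relationships tolerate coarser grids; the four complex periodic
# types need finer ones to resolve their oscillations
.equitability_alpha <- function() {
  c(
    linear = 0.2, exponential = 0.2, triangle_composite = 0.2,
    parabolic = 0.3, sine = 0.3,
    periodic_plus_linear = 0.5, sin_fourier = 0.5,
    sin_nonfourier = 0.5, sin_varying = 0.5
  )
}

.resolve_alpha <- function(alpha, types, default_map) {
  if (is.null(alpha)) alpha <- default_map
  if (length(alpha) == 1L && is.null(names(alpha))) {
    alpha <- stats::setNames(rep(as.numeric(alpha), length(types)), types)
  }
  missing <- setdiff(types, names(alpha))
  if (length(missing)) {
    abort(sprintf("no alpha supplied for type(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "maxassoc_error_parameter")
  }
  vapply(alpha[types], .check_alpha, numeric(1))
}

# derived base seed per sweep row, independent of loop order
.row_seed <- function(seed, i, j) {
  as.integer((abs(as.double(seed)) * 2654435761 + 97003 * i + 193 * j) %%
               2147483647) + 1L
}

.sweep_row <- function(type, alpha, repeats, seed, generator) {
  avg <- mac_average(generator, alpha = alpha, repeats = repeats, seed = seed)
  tibble::tibble(
    alpha = alpha, repeats = repeats,
    mean_mac = avg$mean_mac, sd_mac = avg$sd_mac, runs = avg$runs
  )
}

#' Generality sweep: mean MAC across data sizes and relationship types
#'
#' For every combination of relationship type and data size, draws fresh
#' data each repeat (both the x-sample and the clustering seeds vary),
#' computes the MAC, and averages. A measure with good generality drives
#' the mean toward 1 for the functional types as `n` grows, and toward 0
#' for the random type.
#'
#' Scale defaults are desk-sized (sizes up to 2000, 10 repeats); pass
#' `paper_scale = TRUE` for the full protocol (13 sizes up to 10000,
#' 50 repeats).
#'
#' @param types relationship types to sweep (default: all ten).
#' @param sizes integer vector of data sizes; `NULL` for the scale default.
#' @param alpha named vector mapping type to grid-budget exponent, or a
#'   single unnamed value for all types; `NULL` for the defaults
#'   (0.75 for the nine functional types, 0.45 for `random`).
#' @param repeats runs to average per cell; `NULL` for the scale default.
#' @param seed integer base seed; the whole sweep is reproducible from it.
#' @param paper_scale use the full-protocol sizes and repeats.
#' @return a `mac_sweep` tibble with one row per (type, n): columns `type`,
#'   `n`, `alpha`, `repeats`, `mean_mac`, `sd_mac`, `runs` (list-column of
#'   per-run tibbles).
#' @export
sweep_generality <- function(types = relationship_types(), sizes = NULL,
                             alpha = NULL, repeats = NULL, seed = 1L,
                             paper_scale = FALSE) {
  types <- match.arg(types, .RELATIONSHIPS, several.ok = TRUE)
  sizes <- as.integer(sizes %||%
    if (paper_scale) .PAPER_SIZES else .PAPER_SIZES[.PAPER_SIZES <= 2000L])
  repeats <- as.integer(repeats %||% if (paper_scale) 50L else 10L)
  alpha <- .resolve_alpha(alpha, types, .generality_alpha())

  grid <- tidyr::expand_grid(type = types, n = sizes)
  out <- purrr::pmap_dfr(
    list(grid$type, grid$n, seq_len(nrow(grid))),
    function(ty, n, i) {
      gen <- function(s) simulate_pair(ty, n = n, seed = s)
      row <- .sweep_row(ty, alpha[[ty]], repeats, .row_seed(seed, i, 0L), gen)
      tibble::tibble(type = ty, n = n) |> dplyr::bind_cols(row)
    }
  )
  structure(out, class = c("mac_sweep", class(out)), sweep = "generality")
}

#' Equitability sweep: mean MAC across noise levels and relationship types
#'
#' For every functional relationship type and noise level, generates data
#' at a fixed size, injects uniform vertical noise calibrated so that
#' `1 - R^2` equals the level, computes the MAC, and averages over repeats.
#' An equitable measure scores different relationship types similarly at
#' equal noise, and decreases as noise grows.
#'
#' Scale defaults are desk-sized (n = 1000, levels 0/0.3/0.6/0.9,
#' 10 repeats); pass `paper_scale = TRUE` for the full protocol (n = 4000,
#' levels 0 to 1 by 0.1, 50 repeats).
#'
#' @inheritParams sweep_generality
#' @param types functional relationship types (default: the nine
#'   deterministic ones).
#' @param n fixed data size; `NULL` for the scale default.
#' @param levels noise levels in \[0, 1\]; `NULL` for the scale default.
#' @param alpha named type-to-alpha map or single value; `NULL` for the
#'   defaults (0.2 simple, 0.3 intermediate, 0.5 complex periodic types).
#' @param x_sampling passed to [simulate_pair()].
#' @return a `mac_sweep` tibble with one row per (type, level): columns
#'   `type`, `level`, `alpha`, `repeats`, `mean_mac`, `sd_mac`, `runs`.
#' @export
sweep_equitability <- function(types = relationship_types(deterministic = TRUE),
                               n = NULL, levels = NULL, alpha = NULL,
                               repeats = NULL, seed = 1L,
                               paper_scale = FALSE,
                               x_sampling = "random") {
  types <- match.arg(types, .RELATIONSHIPS, several.ok = TRUE)
  n <- as.integer(n %||% if (paper_scale) 4000L else 1000L)
  levels <- levels %||%
    if (paper_scale) seq(0, 1, by = 0.1) else c(0, 0.3, 0.6, 0.9)
  if (any(levels < 0 | levels > 1)) {
    abort("noise `levels` must lie in [0, 1].",
          class = "maxassoc_error_parameter")
  }
  repeats <- as.integer(repeats %||% if (paper_scale) 50L else 10L)
  alpha <- .resolve_alpha(alpha, types, .equitability_alpha())

  grid <- tidyr::expand_grid(type = types, level = levels)
  out <- purrr::pmap_dfr(
    list(grid$type, grid$level, seq_len(nrow(grid))),
    function(ty, lv, i) {
      gen <- function(s) {
        simulate_pair(ty, n = n, noise = lv, seed = s,
                      x_sampling = x_sampling)
      }
      row <- .sweep_row(ty, alpha[[ty]], repeats, .row_seed(seed, i, 1L), gen)
      tibble::tibble(type = ty, level = lv, n = n) |> dplyr::bind_cols(row)
    }
  )
  structure(out, class = c("mac_sweep", class(out)), sweep = "equitability")
}

#' Agreement metrics between two coefficient vectors
#'
#' Mean squared error, root mean squared error and mean absolute error
#' between two equal-length vectors of association coefficients — the
#' metrics used to compare one dependence measure against another over the
#' same variable pairs.
#'
#' @param estimate,reference equal-length numeric vectors.
#' @return a one-row tibble with `mse`, `rmse`, `mae`, `n`.
#' @examples
#' error_metrics(c(0, 1), c(0.1, 0.8)) # mse 0.025, rmse 0.158, mae 0.15
#' @export
error_metrics <- function(estimate, reference) {
  if (length(estimate) != length(reference)) {
    abort("`estimate` and `reference` must have the same length.",
          class = "maxassoc_error_input")
  }
  if (length(estimate) < 1L) {
    abort("vectors must contain at least one value.",
          class = "maxassoc_error_input")
  }
  d <- as.double(estimate) - as.double(reference)
  mse <- mean(d^2)
  tibble::tibble(mse = mse, rmse = sqrt(mse), mae = mean(abs(d)),
                 n = length(d))
}

#' Plot a sweep of mean MAC values
#'
#' Generality sweeps are drawn against data size (log axis); equitability
#' sweeps against noise level. One line per relationship type.
#'
#' @param object a `mac_sweep` tibble from [sweep_generality()] or
#'   [sweep_equitability()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mac_sweep
#' @export
autoplot.mac_sweep <- function(object, ...) {
  kind <- attr(object, "sweep")
  if (identical(kind, "generality")) {
    p <- ggplot2::ggplot(object, ggplot2::aes(
      x = .data$n, y = .data$mean_mac, colour = .data$type
    )) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "data size n", y = "mean MAC")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(
      x = .data$level, y = .data$mean_mac, colour = .data$type
    )) +
      ggplot2::labs(x = "noise level (1 - R²)", y = "mean MAC")
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
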