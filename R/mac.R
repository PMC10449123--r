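#' Maximum-grid budget
#'
#' The grid search is bounded by the maximum number of grids
#' `MG = max(4, floor(n^alpha))`: the product of the two bin counts of any
#' candidate shape may not exceed MG. Larger `alpha` admits finer grids.
#'
#' @param n number of data points (>= 2).
#' @param alpha grid-budget exponent in \[0, 1\].
#' @return an integer >= 4.
#' @examples
#' compute_mg(10000, 0.75) # 1000
#' compute_mg(2, 0.5)      # 4 (lower bound clamps)
#' @export
compute_mg <- function(n, alpha) {
  .stopifnot_scalar_number(n, "n")
  if (n < 2) {
    abort("`n` must be at least 2.", class = "maxassoc_error_input")
  }
  .check_alpha(alpha)
  # the 1e-9 guard keeps exact integer powers (e.g. 10000^0.75) from
  # flooring one below their analytic value
  max(4L, as.integer(floor(n^alpha + 1e-9)))
}

#' Enumerate admissible grid shapes under an MG budget
#'
#' For every integer `s` in `[2, floor(mg/2)]` the companion bin count is
#' `t = floor(mg/s)` (so `s * t <= mg`; exact division would leave a prime
#' budget with no shapes at all). Shapes with `t < 2` are dropped, and the
#' set is closed under transposition — each `(s, t)` is accompanied by
#' `(t, s)`, which also respects the budget — so that the measure is exactly
#' symmetric in its two arguments.
#'
#' @param mg integer grid budget, >= 4.
#' @return a tibble with integer columns `s` and `t`, ordered by `s` then `t`.
#' @examples
#' enumerate_shapes(4)  # a single 2x2 shape
#' enumerate_shapes(10) # (2,4) (2,5) (3,3) (4,2) (5,2)
#' @export
enumerate_shapes <- function(mg) {
  .stopifnot_scalar_number(mg, "mg")
  if (mg < 4) {
    abort("`mg` must be at least 4.", class = "maxassoc_error_parameter")
  }
  mg <- as.integer(mg)
  s <- 2:(mg %/% 2L)
  t <- mg %/% s
  keep <- t >= 2L
  s <- s[keep]
  t <- t[keep]
  shapes <- unique(rbind(cbind(s, t), cbind(s = t, t = s)))
  shapes <- shapes[order(shapes[, 1L], shapes[, 2L]), , drop = FALSE]
  tibble::tibble(s = as.integer(shapes[, 1L]), t = as.integer(shapes[, 2L]))
}

.mac_fit <- function(mac, best_shape, per_shape, mg, alpha, n, seed,
                     degenerate = FALSE) {
  structure(
    list(
      mac = mac,
      best_shape = best_shape,
      per_shape = per_shape,
      mg = mg,
      alpha = alpha,
      n = n,
      seed = seed,
      degenerate = degenerate,
      n_valid_shapes = if (nrow(per_shape)) sum(per_shape$n_valid_cells > 0L) else 0L
    ),
    class = "mac_fit"
  )
}

#' Maximal association coefficient between two variables
#'
#' Computes the MAC: each admissible `s x t` grid shape within the budget
#' `MG = max(4, floor(n^alpha))` is scored by the association coefficient
#' `AC = sum_i w_i |p_i|`, the area-weighted sum of per-cell absolute
#' Pearson coefficients over the occupied, non-degenerate cells; the MAC is
#' the maximum AC over shapes. A value of 0 indicates no detectable
#' association, 1 a perfect (piecewise-linear) one.
#'
#' Cells with a single point or zero variance in either coordinate are
#' excluded and the area weights renormalized over the remainder; a shape
#' with no surviving cell scores 0; a constant variable yields MAC 0 with a
#' degenerate flag. Ties in the maximum are broken toward the smallest `s`
#' (then smallest `t`). One integer `seed` fully determines the run: the
#' binning of a variable into `k` bins uses a stream derived from
#' `(seed, k)`, shared across shapes and across the two variables, which
#' also makes the coefficient exactly symmetric: `mac(d, x, y)` and
#' `mac(d, y, x)` agree under the same seed.
#'
#' @param data a data frame, or anything coercible via [dplyr::pull()].
#' @param x,y column names (bare or quoted) of the two numeric variables.
#' @param alpha grid-budget exponent in \[0, 1\]; the default 0.6 balances
#'   resolution against variance (and gives an `O(n^1.6)` search).
#' @param mg optional explicit grid budget (>= 4), overriding
#'   [compute_mg()].
#' @param seed integer seed driving every K-means restart.
#' @return an object of class `mac_fit` with elements `mac`, `best_shape`,
#'   `per_shape` (tibble of all shape scores), `mg`, `alpha`, `n`, `seed`,
#'   `degenerate`, `n_valid_shapes`. Use [tidy()] for per-shape scores,
#'   [glance()] for a one-row summary, and [ggplot2::autoplot()] to plot.
#' @examples
#' d <- data.frame(x = seq(0, 1, length.out = 50))
#' d$y <- 2 * d$x + 1
#' mac(d, x, y, alpha = 0.75, seed = 1)$mac # exactly 1
#' @export
mac <- function(data, x = "x", y = "y", alpha = 0.6, mg = NULL, seed = 1L) {
  xv <- .as_numeric_column(data, {{ x }}, "x")
  yv <- .as_numeric_column(data, {{ y }}, "y")
  keep <- !(is.na(xv) | is.na(yv))
  if (!all(keep)) {
    inform(sprintf("dropped %d row(s) with missing values.", sum(!keep)))
    xv <- xv[keep]
    yv <- yv[keep]
  }
  n <- length(xv)
  if (n < 2L) {
    abort("need at least 2 complete observations.",
          class = "maxassoc_error_input")
  }
  .check_alpha(alpha)
  if (!is.null(mg)) {
    .stopifnot_scalar_number(mg, "mg")
    if (mg < 4) {
      abort("`mg` override must be at least 4.",
            class = "maxassoc_error_parameter")
    }
  }
  empty_shapes <- tibble::tibble(
    s = integer(), t = integer(), ac = double(),
    n_cells = integer(), n_valid_cells = integer()
  )
  mg_used <- if (is.null(mg)) compute_mg(n, alpha) else as.integer(mg)
  if (length(unique(xv)) < 2L || length(unique(yv)) < 2L) {
    return(.mac_fit(0, c(s = NA_integer_, t = NA_integer_), empty_shapes,
                    mg_used, alpha, n, seed, degenerate = TRUE))
  }

  shapes <- enumerate_shapes(mg_used)
  ks <- sort(unique(c(shapes$s, shapes$t)))
  bin_x <- bin_y <- vector("list", max(ks))
  for (k in ks) {
    bin_x[[k]] <- bin_kmeans(xv, k, seed = .subseed(seed, k))
    bin_y[[k]] <- bin_kmeans(yv, k, seed = .subseed(seed, k))
  }

  ac <- numeric(nrow(shapes))
  n_cells <- n_valid <- integer(nrow(shapes))
  for (i in seq_len(nrow(shapes))) {
    sc <- .ac_shape(bin_x[[shapes$s[i]]], bin_y[[shapes$t[i]]], xv, yv)
    ac[i] <- sc$ac
    n_cells[i] <- sc$n_cells
    n_valid[i] <- sc$n_valid
  }
  per_shape <- tibble::tibble(
    s = shapes$s, t = shapes$t, ac = ac,
    n_cells = n_cells, n_valid_cells = n_valid
  )
  best <- which(ac == max(ac))[1L] # shapes ordered by s then t: smallest s wins
  .mac_fit(ac[best],
           c(s = shapes$s[best], t = shapes$t[best]),
           per_shape, mg_used, alpha, n, seed)
}

#' Average the MAC over repeated seeded runs
#'
#' Runs [mac()] `repeats` times with seeds `seed, seed + 1, ...` and
#' averages the coefficients, damping the K-means (and, optionally, data)
#' randomness. `data` may be a fixed data frame, in which case only the
#' clustering seeds vary, or a generator `function(seed)` returning a fresh
#' data frame per run, in which case the data are redrawn each repeat with
#' the same seed that drives that run's clustering.
#'
#' @inheritParams mac
#' @param data a data frame or a `function(seed)` returning one.
#' @param repeats number of runs (>= 1).
#' @return a one-row tibble with `mean_mac`, `sd_mac`, `repeats`, `alpha`,
#'   and a `runs` list-column holding the per-run tibble
#'   (`run`, `seed`, `mac`, `best_s`, `best_t`).
#' @examples
#' gen <- function(seed) simulate_pair("linear", n = 100, seed = seed)
#' mac_average(gen, alpha = 0.75, repeats = 3, seed = 1)$mean_mac # 1
#' @export
mac_average <- function(data, x = "x", y = "y", alpha = 0.6, mg = NULL,
                        repeats = 50L, seed = 1L) {
  .stopifnot_scalar_number(repeats, "repeats")
  if (repeats < 1) {
    abort("`repeats` must be at least 1.", class = "maxassoc_error_parameter")
  }
  repeats <- as.integer(repeats)
  runs <- purrr::map_dfr(seq_len(repeats), function(i) {
    s_i <- as.integer(seed) + i - 1L
    d <- if (is.function(data)) data(s_i) else data
    fit <- mac(d, {{ x }}, {{ y }}, alpha = alpha, mg = mg, seed = s_i)
    tibble::tibble(
      run = i, seed = s_i, mac = fit$mac,
      best_s = fit$best_shape[["s"]], best_t = fit$best_shape[["t"]]
    )
  })
  tibble::tibble(
    mean_mac = mean(runs$mac),
    sd_mac = if (repeats > 1L) stats::sd(runs$mac) else 0,
    repeats = repeats,
    alpha = alpha,
    runs = list(runs)
  )
}
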