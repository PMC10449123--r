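#' Bin a numeric variable into contiguous intervals by 1-D K-means
#'
#' Discretizes one variable into at most `k` contiguous bins by Lloyd's
#' algorithm with squared-distance-weighted ("k-means++"-style) seeding.
#' Because the data are one-dimensional, nearest-centre assignment with
#' ascending-sorted centres yields contiguous interval bins; bin labels are
#' ordered so that bin 1 holds the smallest values. Interval edges are the
#' midpoints of consecutive sorted centres, with the outer edges at the
#' observed minimum and maximum (the Voronoi boundaries of 1-D K-means).
#'
#' The randomness contract is part of the definition: one restart consumes
#' exactly `k` uniform deviates (one per centre pick; the first centre is a
#' uniform draw over points, subsequent centres are drawn with probability
#' proportional to the squared distance to the nearest chosen centre), runs
#' `n_restarts` restarts in order, and keeps the restart with strictly
#' smallest within-cluster sum of squares. Lloyd iterations are
#' deterministic; an empty cluster is reseeded once at the point farthest
#' from its assigned centre, and dropped if it recurs (so `k_effective` can
#' fall below `k`). `k` is first capped at the number of distinct values.
#'
#' @param values numeric vector, at least 2 elements and 2 distinct values.
#' @param k requested number of bins, an integer >= 2.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   consumed.
#' @param n_restarts,max_iter,tol clustering controls: number of seeded
#'   restarts, maximum Lloyd iterations per restart, and the convergence
#'   tolerance on the maximum centre movement.
#' @return an object of class `mac_binning`: a list with `k_requested`,
#'   `k_effective`, `assignments` (1-based bin label per point, ordered so
#'   bin 1 holds the smallest values), `edges` (strictly increasing numeric
#'   vector of length `k_effective + 1`), `centers`, `sizes`, and `wcss`.
#' @examples
#' b <- bin_kmeans(c(0, 0.1, 0.9, 1), k = 2, seed = 1)
#' b$assignments # 1 1 2 2
#' b$edges       # 0, 0.5, 1
#' @export
bin_kmeans <- function(values, k, seed = NULL, n_restarts = 10L,
                       max_iter = 300L, tol = 1e-6) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort("`values` must be a numeric vector with at least 2 elements.",
          class = "maxassoc_error_input")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite and free of missing values.",
          class = "maxassoc_error_input")
  }
  .stopifnot_scalar_number(k, "k")
  if (k < 2) {
    abort("`k` must be at least 2.", class = "maxassoc_error_parameter")
  }
  values <- as.double(values)
  n_distinct <- length(unique(values))
  if (n_distinct < 2L) {
    abort("all values are identical; a constant variable cannot be binned.",
          class = "maxassoc_error_constant")
  }
  k_req <- as.integer(k)
  k_eff <- min(k_req, n_distinct)

  run <- function() .kmeans_1d(values, k_eff, n_restarts, max_iter, tol)
  fit <- if (is.null(seed)) run() else with_seed(seed, run())

  n <- length(values)
  o <- order(values)
  assignments <- integer(n)
  assignments[o] <- rep.int(seq_along(fit$counts), fit$counts)
  structure(
    list(
      k_requested = k_req,
      k_effective = length(fit$centers),
      assignments = assignments,
      edges = bin_edges(fit$centers, min(values), max(values)),
      centers = fit$centers,
      sizes = fit$counts,
      wcss = fit$wcss
    ),
    class = "mac_binning"
  )
}

#' Interval edges from sorted cluster centres
#'
#' Interior edge `i` is the midpoint of centres `i` and `i + 1`; the outer
#' edges are the observed data range. With centres sorted ascending these are
#' the 1-D Voronoi boundaries, so every point lies inside its bin's interval.
#'
#' @param centers strictly increasing numeric vector of cluster centres.
#' @param data_min,data_max observed range of the variable.
#' @return strictly increasing numeric vector of length `length(centers) + 1`.
#' @examples
#' bin_edges(c(0.25, 0.75), 0, 1) # 0 0.5 1
#' bin_edges(c(0.1, 0.5, 0.9), 0, 1) # 0 0.3 0.7 1
#' @export
bin_edges <- function(centers, data_min, data_max) {
  k <- length(centers)
  if (k >= 2L && any(diff(centers) <= 0)) {
    abort("cluster centres must be strictly increasing (duplicate centres give a degenerate binning).",
          class = "maxassoc_error_degenerate")
  }
  edges <- if (k == 1L) {
    c(data_min, data_max)
  } else {
    c(data_min, (centers[-k] + centers[-1]) / 2, data_max)
  }
  if (any(diff(edges) <= 0)) {
    abort("bin edges are not strictly increasing; binning is degenerate.",
          class = "maxassoc_error_degenerate")
  }
  edges
}

# Engine wrapper around the compiled 1-D K-means (src/kmeans1d.cpp). The
# RNG contract — exactly k uniform deviates per seeded restart, restarts in
# order, strictly-better WCSS wins — is documented there and mirrored by
# the pure-R reference implementation in the test suite.
.kmeans_1d <- function(values, k, n_restarts, max_iter, tol) {
  fit <- cpp_kmeans1d(values, as.integer(k), as.integer(n_restarts),
                      as.integer(max_iter), tol)
  list(centers = fit$centers, counts = fit$counts, wcss = fit$wcss)
}

#' @export
print.mac_binning <- function(x, ...) {
  cat(sprintf(
    "<mac_binning> %d bin(s) (requested %d) over %d points\n",
    x$k_effective, x$k_requested, length(x$assignments)
  ))
  cat("edges:", format(x$edges, digits = 6), "\n")
  invisible(x)
}
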