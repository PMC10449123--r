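# Benchmark relationship types and R^2-calibrated uniform vertical noise.

.RELATIONSHIPS <- c(
  "linear", "exponential", "triangle_composite", "sine", "parabolic",
  "periodic_plus_linear", "sin_fourier", "sin_nonfourier", "sin_varying",
  "random"
)

#' Names of the benchmark relationship types
#'
#' @param deterministic if `TRUE`, drop the `random` type and return only
#'   the nine functional relationships.
#' @return a character vector of type names accepted by [simulate_pair()].
#' @export
relationship_types <- function(deterministic = FALSE) {
  if (deterministic) setdiff(.RELATIONSHIPS, "random") else .RELATIONSHIPS
}

# y as a function of x in [0, 1] for the nine functional types
.relationship_y <- function(type, x) {
  switch(type,
    linear = 2 * x + 1,
    exponential = 4^(x - 0.5),
    triangle_composite = sin(0.5 * pi * x^2),
    sine = sin(2 * pi * x),
    parabolic = (x - 0.5)^2 + 4,
    periodic_plus_linear = sin(10 * pi * x) + x,
    sin_fourier = sin(16 * pi * x),
    sin_nonfourier = sin(13 * pi * x),
    sin_varying = sin(7 * pi * x * (1 + x)),
    abort(sprintf("unknown relationship type '%s'.", type),
          class = "maxassoc_error_parameter")
  )
}

#' Calibrate the amplitude of uniform vertical noise to a target R-squared
#'
#' Finds, by bisection, the amplitude `a` such that the squared Pearson
#' correlation between `y_true` and `y_true + a * noise` hits `target_r2`
#' within `tolerance`. The unit noise draw is fixed and rescaled by `a`, so
#' the achieved R-squared is monotone in `a` and the bisection converges.
#'
#' @param y_true non-constant numeric vector of true responses.
#' @param target_r2 target squared correlation in (0, 1\].
#' @param noise fixed unit noise draw, same length as `y_true`; if `NULL`,
#'   drawn as `U(-0.5, 0.5)` using `seed`.
#' @param seed integer seed used only when `noise` is `NULL`.
#' @param tolerance calibration tolerance on the achieved R-squared.
#' @param max_iter maximum bisection iterations.
#' @return the scalar amplitude, with the achieved R-squared in attribute
#'   `achieved_r2`.
#' @export
calibrate_noise_amplitude <- function(y_true, target_r2, noise = NULL,
                                      seed = 1L, tolerance = 0.01,
                                      max_iter = 60L) {
  if (!is.numeric(y_true) || length(y_true) < 3L) {
    abort("`y_true` must be numeric with at least 3 elements.",
          class = "maxassoc_error_input")
  }
  if (stats::sd(y_true) == 0) {
    abort("`y_true` is constant; R-squared is undefined.",
          class = "maxassoc_error_constant")
  }
  .stopifnot_scalar_number(target_r2, "target_r2")
  if (target_r2 <= 0 || target_r2 > 1) {
    abort("`target_r2` must lie in (0, 1].",
          class = "maxassoc_error_parameter")
  }
  if (target_r2 == 1) {
    return(structure(0, achieved_r2 = 1))
  }
  if (is.null(noise)) {
    noise <- with_seed(seed, stats::runif(length(y_true)) - 0.5)
  }
  if (length(noise) != length(y_true)) {
    abort("`noise` must match the length of `y_true`.",
          class = "maxassoc_error_input")
  }
  r2_at <- function(a) {
    suppressWarnings(stats::cor(y_true, y_true + a * noise))^2
  }
  # bracket: grow hi until the achieved R^2 falls below target
  hi <- stats::sd(y_true)
  it <- 0L
  while (r2_at(hi) > target_r2 && it < max_iter) {
    hi <- hi * 2
    it <- it + 1L
  }
  if (r2_at(hi) > target_r2 + tolerance) {
    abort(sprintf(
      "noise calibration failed: R^2 floor %.4f above target %.4f (the noise draw is too correlated with y).",
      r2_at(hi), target_r2
    ), class = "maxassoc_error_calibration")
  }
  lo <- 0
  a <- hi
  for (i in seq_len(max_iter)) {
    a <- (lo + hi) / 2
    r2 <- r2_at(a)
    if (abs(r2 - target_r2) <= tolerance) {
      return(structure(a, achieved_r2 = r2))
    }
    if (r2 > target_r2) lo <- a else hi <- a
  }
  abort(sprintf(
    "noise calibration did not converge in %d iterations (last R^2 %.4f, target %.4f).",
    max_iter, r2_at(a), target_r2
  ), class = "maxassoc_error_calibration")
}

#' Add R-squared-calibrated uniform vertical noise to a response
#'
#' Perturbs only the `y` column (the predictor is never touched). The noise
#' `level` is defined as `1 - R^2`, where `R^2` is the squared Pearson
#' correlation between the perturbed and true y-values: level 0 leaves `y`
#' unchanged; a level in (0, 1) adds zero-centred uniform noise whose
#' amplitude is calibrated so the achieved R-squared is `1 - level` within
#' `tolerance`; level 1 replaces `y` outright with independent uniform
#' values spanning the observed y-range (additive noise only reaches
#' R-squared 0 asymptotically).
#'
#' @param data a data frame containing the response column.
#' @param level noise level in \[0, 1\].
#' @param y column name of the response.
#' @param seed integer seed for the noise draw.
#' @param tolerance calibration tolerance on the achieved R-squared.
#' @return `data` with the response perturbed, carrying the attribute
#'   `achieved_r2`.
#' @export
add_vertical_noise <- function(data, level, y = "y", seed = 1L,
                               tolerance = 0.01) {
  .stopifnot_scalar_number(level, "level")
  if (level < 0 || level > 1) {
    abort("`level` must lie in [0, 1].", class = "maxassoc_error_parameter")
  }
  y_name <- .col_name(rlang::enquo(y))
  if (!y_name %in% names(data)) {
    abort(sprintf("column `%s` not found in `data`.", y_name),
          class = "maxassoc_error_input")
  }
  y_true <- .as_numeric_column(data, {{ y }}, "y")
  out <- tibble::as_tibble(data)
  if (level == 0) {
    attr(out, "achieved_r2") <- 1
    return(out)
  }
  if (level == 1) {
    y_new <- with_seed(seed,
      stats::runif(length(y_true), min(y_true), max(y_true)))
    out[[y_name]] <- y_new
    attr(out, "achieved_r2") <- suppressWarnings(stats::cor(y_true, y_new))^2
    return(out)
  }
  e <- with_seed(seed, stats::runif(length(y_true)) - 0.5)
  a <- calibrate_noise_amplitude(y_true, target_r2 = 1 - level, noise = e,
                                 tolerance = tolerance)
  out[[y_name]] <- y_true + as.numeric(a) * e
  attr(out, "achieved_r2") <- attr(a, "achieved_r2")
  out
}

#' Simulate a benchmark variable pair
#'
#' Generates `n` points of one of ten benchmark relationship types on the
#' unit interval: x is drawn i.i.d. uniform on \[0, 1\] (or laid on an even
#' grid), y follows the type's formula — `2x + 1` (linear), `4^(x - 0.5)`
#' (exponential), `sin(0.5 pi x^2)` (triangle composite),
#' `sin(2 pi x)` (sine), `(x - 0.5)^2 + 4` (parabolic),
#' `sin(10 pi x) + x` (periodic plus linear), `sin(16 pi x)` /
#' `sin(13 pi x)` / `sin(7 pi x (1 + x))` (sinusoidal at Fourier,
#' non-Fourier and varying frequency) — or, for type `random`, y is an
#' independent uniform draw. Optional uniform vertical noise is injected by
#' [add_vertical_noise()] at the requested `1 - R^2` level.
#'
#' @param type one of [relationship_types()].
#' @param n number of points.
#' @param noise noise level in \[0, 1\] (`1 - R^2`); 0 for a noise-free pair.
#' @param seed integer seed; the same spec and seed reproduce the pair
#'   bit-identically.
#' @param x_sampling `"random"` for i.i.d. uniform x (the default),
#'   `"grid"` for an even grid over \[0, 1\].
#' @param tolerance calibration tolerance passed to [add_vertical_noise()].
#' @return a tibble with columns `x`, `y`, `y_true`, carrying attributes
#'   `type`, `noise_level`, `achieved_r2`.
#' @examples
#' d <- simulate_pair("sine", n = 200, seed = 7)
#' range(d$x) # within [0, 1]
#' @export
simulate_pair <- function(type, n, noise = 0, seed = 1L,
                          x_sampling = c("random", "grid"),
                          tolerance = 0.01) {
  type <- match.arg(type, .RELATIONSHIPS)
  x_sampling <- match.arg(x_sampling)
  .stopifnot_scalar_number(n, "n")
  if (n < 1) {
    abort("`n` must be at least 1.", class = "maxassoc_error_parameter")
  }
  n <- as.integer(n)
  base <- with_seed(seed, {
    x <- if (x_sampling == "random") stats::runif(n) else {
      if (n == 1L) 0.5 else seq(0, 1, length.out = n)
    }
    y_true <- if (type == "random") stats::runif(n) else {
      .relationship_y(type, x)
    }
    tibble::tibble(x = x, y = y_true, y_true = y_true)
  })
  out <- if (noise > 0) {
    # a distinct derived seed keeps the noise draw independent of x
    add_vertical_noise(base, level = noise, y = "y",
                       seed = .subseed(seed, 104729L), tolerance = tolerance)
  } else {
    attr(base, "achieved_r2") <- 1
    base
  }
  attr(out, "type") <- type
  attr(out, "noise_level") <- noise
  out
}
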