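# S3 methods for mac_fit: print, broom-style tidy/glance, autoplot.

#' @export
print.mac_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf(
      "<mac_fit> MAC = 0 (degenerate: a constant variable), n = %d\n", x$n
    ))
    return(invisible(x))
  }
  cat(sprintf(
    "<mac_fit> MAC = %.4f at %d x %d grid (MG = %d, alpha = %g, n = %d)\n",
    x$mac, x$best_shape[["s"]], x$best_shape[["t"]], x$mg, x$alpha, x$n
  ))
  cat(sprintf("  %d shape(s) searched, %d with at least one scoring cell\n",
              nrow(x$per_shape), x$n_valid_shapes))
  invisible(x)
}

#' Tidy the per-shape association coefficients of a MAC fit
#'
#' @param x a `mac_fit` from [mac()].
#' @param ... unused.
#' @return a tibble with one row per searched grid shape: `s`, `t`, `ac`,
#'   `n_cells`, `n_valid_cells`, `best` (logical).
#' @method tidy mac_fit
#' @export
tidy.mac_fit <- function(x, ...) {
  out <- x$per_shape
  out$best <- FALSE
  if (nrow(out)) {
    out$best <- out$s == x$best_shape[["s"]] & out$t == x$best_shape[["t"]]
  }
  out
}

#' One-row summary of a MAC fit
#'
#' @param x a `mac_fit` from [mac()].
#' @param ... unused.
#' @return a one-row tibble: `mac`, `best_s`, `best_t`, `mg`, `alpha`, `n`,
#'   `n_shapes`, `n_valid_shapes`, `degenerate`, `seed`.
#' @method glance mac_fit
#' @export
glance.mac_fit <- function(x, ...) {
  tibble::tibble(
    mac = x$mac,
    best_s = x$best_shape[["s"]],
    best_t = x$best_shape[["t"]],
    mg = x$mg,
    alpha = x$alpha,
    n = x$n,
    n_shapes = nrow(x$per_shape),
    n_valid_shapes = x$n_valid_shapes,
    degenerate = x$degenerate,
    seed = as.integer(x$seed)
  )
}

#' Plot the association-coefficient profile of a MAC fit
#'
#' One point per searched grid shape (x-axis: bins on the first variable),
#' with the maximizing shape highlighted.
#'
#' @param object a `mac_fit` from [mac()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mac_fit
#' @export
autoplot.mac_fit <- function(object, ...) {
  d <- tidy(object)
  if (!nrow(d)) {
    abort("nothing to plot: degenerate fit with no searched shapes.",
          class = "maxassoc_error_input")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s, y = .data$ac)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$t)), alpha = 0.8) +
    ggplot2::geom_point(
      data = d[d$best, , drop = FALSE],
      shape = 21, size = 3, stroke = 1, colour = "red", fill = NA
    ) +
    ggplot2::labs(
      x = "bins on x (s)", y = "association coefficient AC(s, t)",
      colour = "bins on y (t)",
      title = sprintf("MAC = %.3f at %d x %d (MG = %d, alpha = %g)",
                      object$mac, object$best_shape[["s"]],
                      object$best_shape[["t"]], object$mg, object$alpha)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
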