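# Delimited-table input and the pairwise association matrix.

#' Read an aligned variable pair from a delimited table
#'
#' Reads a CSV/TSV (header row required), checks that the two named
#' columns are numeric, and drops rows with a missing value in either
#' column (pairwise deletion; the count of dropped rows is messaged).
#'
#' @param path file path.
#' @param x,y column names of the two variables.
#' @param delimiter field delimiter; `NULL` guesses from the file.
#' @return a tibble with the two selected numeric columns (named as in the
#'   file), at least 2 rows.
#' @export
read_pair <- function(path, x = "x", y = "y", delimiter = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "maxassoc_error_io")
  }
  # columns are read as text and parsed with R's strtod so that values
  # written at full precision round-trip bit-exactly
  tab <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  out <- list()
  for (col in c(x, y)) {
    if (!col %in% names(tab)) {
      abort(sprintf("column `%s` not found in %s.", col, path),
            class = "maxassoc_error_input")
    }
    v <- trimws(as.character(tab[[col]]))
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed) & !is.na(v) & nzchar(v) & v != "NA")
    if (length(bad)) {
      abort(sprintf(
        "column `%s` is not numeric (first offending row: %d).",
        col, bad[1]
      ), class = "maxassoc_error_parse")
    }
    out[[col]] <- parsed
  }
  out <- tibble::as_tibble(out)
  keep <- stats::complete.cases(out)
  if (!all(keep)) {
    inform(sprintf("dropped %d row(s) with missing values.", sum(!keep)))
    out <- out[keep, ]
  }
  if (nrow(out) < 2L) {
    abort("fewer than 2 usable rows after missing-value filtering.",
          class = "maxassoc_error_insufficient")
  }
  out
}

#' Screen every column against a target by averaged MAC
#'
#' Computes the seed-averaged MAC between one target column and every other
#' numeric column of a table — the screening pattern for asking which of
#' many measured variables associates with an outcome. Rows with a missing
#' value in the analyzed pair are dropped pairwise for that pair only.
#'
#' @param data a data frame.
#' @param target name of the target column (bare or quoted).
#' @param alpha grid-budget exponent.
#' @param repeats seeded runs to average per pair.
#' @param seed integer base seed.
#' @param mg optional explicit grid budget.
#' @return a tibble sorted by descending `mean_mac`, one row per screened
#'   column: `target`, `variable`, `mean_mac`, `sd_mac`, `best_s`,
#'   `best_t`, `mg`, `alpha`, `repeats`, `n_used`, `n_dropped`,
#'   `degenerate`.
#' @export
mac_matrix <- function(data, target, alpha = 0.6, repeats = 50L, seed = 1L,
                       mg = NULL) {
  target_name <- .col_name(rlang::enquo(target))
  if (!target_name %in% names(data)) {
    abort(sprintf("target column `%s` not found.", target_name),
          class = "maxassoc_error_input")
  }
  if (!is.numeric(data[[target_name]])) {
    abort(sprintf("target column `%s` must be numeric.", target_name),
          class = "maxassoc_error_input")
  }
  others <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    target_name)
  if (!length(others)) {
    abort("no numeric columns to screen against the target.",
          class = "maxassoc_error_input")
  }
  rows <- purrr::map_dfr(others, function(v) {
    pair <- data[, c(target_name, v)]
    keep <- stats::complete.cases(pair)
    pair <- pair[keep, ]
    n_used <- nrow(pair)
    if (n_used < 2L) {
      return(tibble::tibble(
        target = target_name, variable = v, mean_mac = NA_real_,
        sd_mac = NA_real_, best_s = NA_integer_, best_t = NA_integer_,
        mg = NA_integer_, alpha = alpha, repeats = as.integer(repeats),
        n_used = n_used, n_dropped = sum(!keep), degenerate = TRUE
      ))
    }
    avg <- mac_average(pair, x = target_name, y = v, alpha = alpha, mg = mg,
                       repeats = repeats, seed = seed)
    first <- mac(pair, x = target_name, y = v, alpha = alpha, mg = mg,
                 seed = seed)
    tibble::tibble(
      target = target_name, variable = v, mean_mac = avg$mean_mac,
      sd_mac = avg$sd_mac, best_s = first$best_shape[["s"]],
      best_t = first$best_shape[["t"]], mg = first$mg, alpha = alpha,
      repeats = as.integer(repeats), n_used = n_used,
      n_dropped = sum(!keep), degenerate = first$degenerate
    )
  })
  dplyr::arrange(rows, dplyr::desc(.data$mean_mac))
}
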