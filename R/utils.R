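# internal helpers: seeding contract and error constructors

#' @importFrom rlang abort inform warn %||%
NULL

# Evaluate `code` under a temporarily seeded RNG, restoring the caller's
# stream afterwards. All user-facing randomness goes through this.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream split: one integer master seed plus the number of bins
# requested fully determines the K-means stream for that binning. The split
# deliberately ignores which variable (x or y) is being binned so that
# mac(x, y) and mac(y, x) bin each variable identically and the measure is
# exactly symmetric under matched seeds.
.subseed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647) * 48271 + 1009 * as.double(k)
  as.integer(s %% 2147483646) + 1L
}

.stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "maxassoc_error_parameter")
  }
}

.check_alpha <- function(alpha) {
  .stopifnot_scalar_number(alpha, "alpha")
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "maxassoc_error_parameter")
  }
  alpha
}

.as_numeric_column <- function(data, col, arg) {
  v <- dplyr::pull(data, {{ col }})
  if (!is.numeric(v)) {
    abort(sprintf("column selected by `%s` must be numeric.", arg),
          class = "maxassoc_error_input")
  }
  as.double(v)
}

# Resolve a user-supplied column argument that may be a bare symbol or a
# character value (possibly computed, e.g. from CLI options).
.col_name <- function(quo) {
  if (rlang::quo_is_symbol(quo)) return(rlang::as_name(quo))
  v <- rlang::eval_tidy(quo)
  if (!is.character(v) || length(v) != 1L) {
    abort("column must be given as a name or a single string.",
          class = "maxassoc_error_input")
  }
  v
}
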