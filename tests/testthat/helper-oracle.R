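# Independent brute-force reference implementation of the maximal
# association coefficient, written naively (per-point loops, nearest-centre
# assignment, mean() per cluster) and sharing no code with the package's
# engine. It follows the same published procedure and the same documented
# randomness contract (one uniform deviate per centre pick, restarts in
# order, strictly-better WCSS wins, the (seed, k) stream split), so matched
# seeds must reproduce the package's results.

oracle_subseed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647) * 48271 + 1009 * as.double(k)
  as.integer(s %% 2147483646) + 1L
}

oracle_nearest <- function(values, cen) {
  vapply(values, function(v) which.min(abs(v - cen)), integer(1))
}

oracle_lloyd <- function(values, cen, max_iter = 300L, tol = 1e-6) {
  reseeded <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (length(cen) == 1L) break
    lab <- oracle_nearest(values, cen)
    cnt <- tabulate(lab, length(cen))
    if (any(cnt == 0L)) {
      if (!reseeded) {
        reseeded <- TRUE
        d <- abs(values - cen[lab])
        o <- order(values)
        far <- o[which.max(d[o])] # first farthest point in sorted order
        cen[which(cnt == 0L)[1L]] <- values[far]
        cen <- sort(cen)
      } else {
        cen <- cen[cnt > 0L]
      }
      if (iter >= max_iter) break
      next
    }
    newc <- vapply(seq_along(cen), function(j) mean(values[lab == j]),
                   numeric(1))
    delta <- max(abs(newc - cen))
    cen <- newc
    if (delta < tol || iter >= max_iter) break
  }
  repeat {
    cen <- unique(cen)
    if (length(cen) == 1L) {
      cen <- mean(values)
      lab <- rep(1L, length(values))
      break
    }
    lab <- oracle_nearest(values, cen)
    cnt <- tabulate(lab, length(cen))
    if (all(cnt > 0L)) break
    cen <- cen[cnt > 0L]
  }
  list(centers = cen, labels = lab,
       wcss = sum((values - cen[lab])^2))
}

oracle_bin <- function(values, k, seed, n_restarts = 10L) {
  k <- min(k, length(unique(values)))
  n <- length(values)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cen <- numeric(k)
    cen[1L] <- values[min(n, floor(stats::runif(1) * n) + 1L)]
    if (k > 1L) {
      for (j in 2:k) {
        d2 <- vapply(values, function(v) min((v - cen[seq_len(j - 1L)])^2),
                     numeric(1))
        cw <- cumsum(d2)
        cen[j] <- values[which(cw >= stats::runif(1) * cw[n])[1L]]
      }
    }
    fit <- oracle_lloyd(values, sort(cen))
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  best$edges <- if (length(best$centers) == 1L) {
    c(min(values), max(values))
  } else {
    k2 <- length(best$centers)
    c(min(values),
      (best$centers[-k2] + best$centers[-1]) / 2,
      max(values))
  }
  best
}

oracle_abs_pearson <- function(xs, ys) {
  if (length(xs) < 2L) return(NA_real_)
  if (length(unique(xs)) == 1L || length(unique(ys)) == 1L) return(NA_real_)
  if (length(xs) == 2L) return(1)
  r <- suppressWarnings(stats::cor(xs, ys))
  if (is.na(r)) NA_real_ else min(abs(r), 1)
}

oracle_shapes <- function(mg) {
  out <- list()
  for (s in 2:(mg %/% 2L)) {
    t <- mg %/% s
    if (t >= 2L) {
      out[[length(out) + 1L]] <- c(s, t)
      out[[length(out) + 1L]] <- c(t, s)
    }
  }
  m <- unique(do.call(rbind, out))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

oracle_ac <- function(xv, yv, bx, by) {
  pairs <- unique(cbind(bx$labels, by$labels))
  areas <- absp <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    in_cell <- bx$labels == pairs[i, 1L] & by$labels == pairs[i, 2L]
    areas[i] <- (bx$edges[pairs[i, 1L] + 1L] - bx$edges[pairs[i, 1L]]) *
      (by$edges[pairs[i, 2L] + 1L] - by$edges[pairs[i, 2L]])
    absp[i] <- oracle_abs_pearson(xv[in_cell], yv[in_cell])
  }
  ok <- !is.na(absp)
  if (!any(ok)) return(0)
  w <- if (sum(areas[ok]) > 0) areas[ok] / sum(areas[ok]) else {
    rep(1 / sum(ok), sum(ok))
  }
  sum(w * absp[ok])
}

oracle_mac <- function(xv, yv, alpha = 0.6, seed = 1L, mg = NULL) {
  n <- length(xv)
  if (is.null(mg)) mg <- max(4L, floor(n^alpha + 1e-9))
  shapes <- oracle_shapes(mg)
  ac <- numeric(nrow(shapes))
  for (i in seq_len(nrow(shapes))) {
    bx <- oracle_bin(xv, shapes[i, 1L], oracle_subseed(seed, shapes[i, 1L]))
    by <- oracle_bin(yv, shapes[i, 2L], oracle_subseed(seed, shapes[i, 2L]))
    ac[i] <- oracle_ac(xv, yv, bx, by)
  }
  max(ac)
}
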