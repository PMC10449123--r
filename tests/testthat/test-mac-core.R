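test_that("the grid budget follows the clamped power law", {
  expect_identical(compute_mg(10000, 0.75), 1000L)
  expect_identical(compute_mg(4000, 0.5), 63L)
  expect_identical(compute_mg(2, 0.5), 4L)
  for (a in c(0, 0.5, 1)) expect_identical(compute_mg(2, a), 4L)
  expect_error(compute_mg(100, 1.2), class = "maxassoc_error_parameter")
  expect_error(compute_mg(100, -0.1), class = "maxassoc_error_parameter")
  expect_error(compute_mg(1, 0.5), class = "maxassoc_error_input")
})

test_that("shape enumeration respects the budget and is transpose-closed", {
  expect_identical(enumerate_shapes(4),
                   tibble::tibble(s = 2L, t = 2L))
  expect_identical(enumerate_shapes(7),
                   tibble::tibble(s = c(2L, 3L), t = c(3L, 2L)))
  expect_identical(
    enumerate_shapes(10),
    tibble::tibble(s = c(2L, 2L, 3L, 4L, 5L), t = c(4L, 5L, 3L, 2L, 2L))
  )
  expect_error(enumerate_shapes(3), class = "maxassoc_error_parameter")
  for (mg in c(4, 9, 13, 24, 63, 100)) {
    sh <- enumerate_shapes(mg)
    expect_true(all(sh$s * sh$t <= mg))
    expect_true(all(sh$s >= 2L & sh$t >= 2L))
    # closed under transposition
    key <- paste(sh$s, sh$t)
    expect_true(all(paste(sh$t, sh$s) %in% key))
    expect_identical(anyDuplicated(key), 0L)
  }
})

test_that("the association coefficient is the area-weighted mean of |r|", {
  # two cells with areas 1 and 3 and |r| of 1 and 0.5: AC = 0.625
  w <- cell_weights(c(1, 3))
  expect_equal(sum(w * c(1, 0.5)), 0.625)
  # constructed grid: linear in each quadrant -> every valid cell |r| = 1
  d <- data.frame(x = c(0.0, 0.1, 0.2, 0.8, 0.9, 1.0))
  d$y <- 3 * d$x - 1
  cells <- mac_cells(d, x, y, s = 2, t = 2, seed = 1)
  expect_true(all(cells$abs_pearson[cells$valid] == 1))
})

test_that("noiseless linear data scores exactly one for any n and alpha", {
  for (case in list(list(n = 10, a = 0.3), list(n = 101, a = 0.6),
                    list(n = 757, a = 1.0))) {
    set.seed(case$n)
    d <- tibble::tibble(x = stats::runif(case$n))
    d$y <- -1.7 * d$x + 0.4 # negative slope: |r| still 1
    fit <- mac(d, x, y, alpha = case$a, seed = 3)
    expect_equal(fit$mac, 1, tolerance = 1e-12)
    expect_true(all(fit$per_shape$ac >= 1 - 1e-12))
  }
})

test_that("constant variables yield a degenerate zero coefficient", {
  d <- data.frame(x = 1:10, y = rep(2, 10))
  fit <- mac(d, x, y, seed = 1)
  expect_identical(fit$mac, 0)
  expect_true(fit$degenerate)
  expect_identical(nrow(fit$per_shape), 0L)
})

test_that("input contracts are enforced", {
  expect_error(mac(data.frame(x = 1, y = 2)), class = "maxassoc_error_input")
  expect_error(mac(data.frame(x = 1:9, y = 1:9), alpha = 2),
               class = "maxassoc_error_parameter")
  expect_error(mac(data.frame(x = 1:9, y = 1:9), mg = 3),
               class = "maxassoc_error_parameter")
  expect_message(
    fit <- mac(data.frame(x = c(1:8, NA), y = c(NA, 2:9)), seed = 1),
    "missing"
  )
  expect_identical(fit$n, 7L)
})

test_that("the reported MAC is the maximum over shapes and lies in [0, 1]", {
  for (s in 1:8) {
    n <- 30 + 10 * s
    set.seed(s)
    d <- tibble::tibble(x = stats::runif(n), y = stats::runif(n))
    fit <- mac(d, x, y, alpha = 0.8, seed = s)
    expect_true(all(fit$per_shape$ac >= 0 & fit$per_shape$ac <= 1))
    expect_equal(fit$mac, max(fit$per_shape$ac))
    best <- fit$per_shape[fit$per_shape$ac == fit$mac, ]
    expect_identical(fit$best_shape[["s"]], min(best$s)) # smallest-s tie rule
  }
})

test_that("the coefficient is symmetric in its arguments under matched seeds", {
  for (s in 1:10) {
    d <- simulate_pair(sample(relationship_types(), 1), n = 40 + 4 * s,
                       noise = (s %% 3) * 0.2, seed = 500 + s)
    a <- mac(d, x, y, alpha = 0.7, seed = s)$mac
    b <- mac(d, y, x, alpha = 0.7, seed = s)$mac
    expect_identical(a, b)
  }
})

test_that("the coefficient is invariant under affine maps of either variable", {
  for (s in 1:6) {
    d <- simulate_pair("sine", n = 50, noise = 0.2, seed = 40 + s)
    base <- mac(d, x, y, alpha = 0.8, seed = s)$mac
    d2 <- dplyr::mutate(d, x = 3 * x - 2, y = -0.5 * y + 7)
    expect_equal(mac(d2, x, y, alpha = 0.8, seed = s)$mac, base,
                 tolerance = 1e-12)
  }
})

test_that("a brute-force reference reproduces the coefficient exactly", {
  set.seed(99)
  for (i in 1:5) {
    n <- sample(12:30, 1)
    d <- simulate_pair(sample(c("linear", "random", "sine"), 1), n,
                       seed = 200 + i)
    m <- sample(4:10, 1)
    sd_ <- sample(1:10000, 1)
    expect_lt(
      abs(mac(d, x, y, mg = m, seed = sd_)$mac -
            oracle_mac(d$x, d$y, seed = sd_, mg = m)),
      1e-12
    )
  }
})

test_that("averaging runs the estimator across consecutive seeds", {
  d <- simulate_pair("linear", n = 60, seed = 3)
  one <- mac_average(d, repeats = 1, seed = 7)
  expect_equal(one$mean_mac, mac(d, seed = 7)$mac)
  expect_identical(one$sd_mac, 0)
  avg <- mac_average(d, repeats = 5, seed = 7)
  runs <- avg$runs[[1]]
  expect_identical(runs$seed, 7L + 0:4)
  expect_equal(avg$mean_mac, mean(runs$mac))
  # generator form redraws data each run and is reproducible
  gen <- function(s) simulate_pair("random", n = 30, seed = s)
  a1 <- mac_average(gen, alpha = 0.5, repeats = 4, seed = 11)
  a2 <- mac_average(gen, alpha = 0.5, repeats = 4, seed = 11)
  expect_identical(a1$runs[[1]], a2$runs[[1]])
  expect_error(mac_average(d, repeats = 0), class = "maxassoc_error_parameter")
})

test_that("tidy, glance and autoplot expose the fit", {
  d <- simulate_pair("parabolic", n = 80, seed = 5)
  fit <- mac(d, alpha = 0.7, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(sum(td$best), 1L)
  expect_equal(td$ac[td$best], fit$mac)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$mac, fit$mac)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_output(print(fit), "MAC")
})
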