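test_that("comparison metrics follow their closed forms", {
  z <- error_metrics(c(0.2, 0.4, 0.9), c(0.2, 0.4, 0.9))
  expect_equal(unlist(z[c("mse", "rmse", "mae")]), c(mse = 0, rmse = 0, mae = 0))
  off <- error_metrics(seq(0, 1, by = 0.25) + 0.1, seq(0, 1, by = 0.25))
  expect_equal(off$mse, 0.01)
  expect_equal(off$rmse, 0.1)
  expect_equal(off$mae, 0.1)
  m <- error_metrics(c(0, 1), c(0.1, 0.8))
  expect_equal(m$mse, 0.025)
  expect_equal(m$rmse, sqrt(0.025), tolerance = 1e-4)
  expect_equal(m$mae, 0.15)
  expect_error(error_metrics(1:3, 1:4), class = "maxassoc_error_input")
})

test_that("rmse squared equals mse and mae never exceeds rmse", {
  for (s in 1:5) {
    set.seed(s)
    a <- stats::runif(20)
    b <- stats::runif(20)
    m <- error_metrics(a, b)
    expect_equal(m$rmse^2, m$mse, tolerance = 1e-12)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("the generality sweep averages fresh draws per repeat", {
  g <- sweep_generality(types = c("linear", "random"), sizes = c(50, 100),
                        repeats = 2, seed = 5)
  expect_identical(nrow(g), 4L)
  expect_identical(vapply(g$runs, nrow, integer(1)), rep(2L, 4))
  expect_equal(g$mean_mac, vapply(g$runs, function(r) mean(r$mac), numeric(1)))
  lin <- g[g$type == "linear", ]
  expect_equal(lin$mean_mac, c(1, 1), tolerance = 1e-12)
  expect_equal(lin$alpha, c(0.75, 0.75))
  expect_equal(g$alpha[g$type == "random"], c(0.45, 0.45))
  # per-repeat data differ (fresh draws), per-run macs need not be equal
  r <- g$runs[[which(g$type == "random" & g$n == 100)]]
  expect_identical(r$seed[2] - r$seed[1], 1L)
  # reproducible end to end
  g2 <- sweep_generality(types = c("linear", "random"), sizes = c(50, 100),
                         repeats = 2, seed = 5)
  expect_identical(g$mean_mac, g2$mean_mac)
})

test_that("the equitability sweep injects calibrated noise per level", {
  e <- sweep_equitability(types = c("linear", "sine"), n = 300,
                          levels = c(0, 0.5), repeats = 2, seed = 4)
  expect_identical(nrow(e), 4L)
  expect_equal(e$mean_mac[e$type == "linear" & e$level == 0], 1,
               tolerance = 1e-12)
  # within each type, noise can only lower the mean coefficient
  for (ty in c("linear", "sine")) {
    expect_lte(e$mean_mac[e$type == ty & e$level == 0.5],
               e$mean_mac[e$type == ty & e$level == 0])
  }
  expect_equal(e$alpha, c(0.2, 0.2, 0.3, 0.3))
  e2 <- sweep_equitability(types = c("linear", "sine"), n = 300,
                           levels = c(0, 0.5), repeats = 2, seed = 4)
  expect_identical(e$mean_mac, e2$mean_mac)
})

test_that("sweep alpha mappings are validated", {
  expect_error(
    sweep_generality(types = "linear", sizes = 50, repeats = 1,
                     alpha = c(sine = 0.5)),
    class = "maxassoc_error_parameter"
  )
  g <- sweep_generality(types = "linear", sizes = 50, repeats = 1,
                        alpha = 0.5, seed = 2)
  expect_equal(g$alpha, 0.5)
  expect_error(
    sweep_equitability(types = "linear", n = 100, levels = 1.5, repeats = 1),
    class = "maxassoc_error_parameter"
  )
})

test_that("sweep results plot as line charts", {
  g <- sweep_generality(types = "linear", sizes = c(20, 50), repeats = 1,
                        seed = 1)
  expect_s3_class(ggplot2::autoplot(g), "ggplot")
  e <- sweep_equitability(types = "linear", n = 100, levels = c(0, 0.5),
                          repeats = 1, seed = 1)
  expect_s3_class(ggplot2::autoplot(e), "ggplot")
})
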