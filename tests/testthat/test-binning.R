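test_that("well-separated clusters split as expected", {
  b <- bin_kmeans(c(0, 0.1, 0.9, 1), k = 2, seed = 1)
  expect_identical(b$assignments, c(1L, 1L, 2L, 2L))
  expect_equal(b$edges, c(0, 0.5, 1))
  expect_identical(b$k_effective, 2L)
})

test_that("invalid inputs are rejected with typed errors", {
  expect_error(bin_kmeans(c(0, 0.5, 1), k = 1), class = "maxassoc_error_parameter")
  expect_error(bin_kmeans(rep(3, 10), k = 2), class = "maxassoc_error_constant")
  expect_error(bin_kmeans(c(1, NA, 2), k = 2), class = "maxassoc_error_input")
  expect_error(bin_kmeans(numeric(1), k = 2), class = "maxassoc_error_input")
})

test_that("uniform grid of 100 points yields four near-equal quarters", {
  # the global optimum is four bins of 25 consecutive points (WCSS
  # 5200/99^2); Lloyd restarts may stop at an adjacent local fixed point,
  # so bins must be contiguous, balanced to +/-1, and within 1% of the
  # optimal WCSS
  v <- seq(0, 1, length.out = 100)
  wcss_opt <- 4 * (25 * (25^2 - 1) / 12) * (1 / 99)^2
  for (s in c(1, 2, 3)) {
    b <- bin_kmeans(v, k = 4, seed = s)
    expect_identical(b$k_effective, 4L)
    expect_identical(sum(b$sizes), 100L)
    expect_true(all(abs(b$sizes - 25L) <= 1L))
    expect_lt(b$wcss, 1.01 * wcss_opt)
    # contiguity: sorted values have non-decreasing labels
    expect_true(!is.unsorted(b$assignments[order(v)]))
  }
})

test_that("bin edges are centre midpoints bounded by the data range", {
  expect_equal(bin_edges(c(0.25, 0.75), 0, 1), c(0, 0.5, 1))
  expect_equal(bin_edges(c(0.1, 0.5, 0.9), 0, 1), c(0, 0.3, 0.7, 1))
  expect_equal(bin_edges(0.4, 0, 1), c(0, 1))
  expect_error(bin_edges(c(0.5, 0.5), 0, 1), class = "maxassoc_error_degenerate")
})

test_that("binning is a partition with interval structure", {
  for (s in 1:5) {
    set.seed(100 + s)
    v <- stats::rnorm(80)
    k <- 2L + s
    b <- bin_kmeans(v, k, seed = s)
    # every label used, contiguous 1..k_effective
    expect_identical(sort(unique(b$assignments)), seq_len(b$k_effective))
    expect_identical(sum(b$sizes), 80L)
    # sorting values sorts labels
    expect_true(!is.unsorted(b$assignments[order(v)]))
    # every value inside its bin interval
    expect_true(all(v >= b$edges[b$assignments] - 1e-12))
    expect_true(all(v <= b$edges[b$assignments + 1L] + 1e-12))
    expect_identical(length(b$edges), b$k_effective + 1L)
    expect_true(all(diff(b$edges) > 0))
  }
})

test_that("identical values always share a bin", {
  v <- c(0, 0, 0.2, 0.2, 0.2, 0.7, 0.7, 1, 1, 1)
  b <- bin_kmeans(v, 3, seed = 4)
  for (u in unique(v)) {
    expect_length(unique(b$assignments[v == u]), 1L)
  }
})

test_that("k beyond the number of distinct values is reduced", {
  v <- rep(c(0, 0.5, 1), times = 4)
  b <- bin_kmeans(v, k = 5, seed = 2)
  expect_lte(b$k_effective, 3L)
  expect_gte(b$k_effective, 2L)
})

test_that("binning is equivariant under positive affine maps of the data", {
  set.seed(7)
  v <- stats::runif(60)
  for (s in 1:3) {
    b0 <- bin_kmeans(v, 4, seed = s)
    b1 <- bin_kmeans(2.5 * v + 3, 4, seed = s)
    expect_identical(b0$assignments, b1$assignments)
    expect_equal(b1$edges, 2.5 * b0$edges + 3, tolerance = 1e-12)
  }
})

test_that("negative scaling reverses labels but preserves the partition", {
  set.seed(8)
  v <- stats::runif(60)
  b0 <- bin_kmeans(v, 4, seed = 2)
  b1 <- bin_kmeans(-v, 4, seed = 2)
  expect_identical(b1$k_effective, b0$k_effective)
  expect_identical(b1$assignments, b0$k_effective + 1L - b0$assignments)
})

test_that("a fixed seed reproduces the binning exactly", {
  set.seed(11)
  v <- stats::rnorm(50)
  b1 <- bin_kmeans(v, 5, seed = 123)
  b2 <- bin_kmeans(v, 5, seed = 123)
  expect_identical(b1, b2)
})
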