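test_that("coarse-graining averages non-overlapping windows and drops the remainder", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(coarse_grain(c(5, 1, 7), 1), c(5, 1, 7))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
  expect_error(coarse_grain(c(1, 2, 3), 0), "scale")
  expect_error(coarse_grain(c(1, 2, 3), 4), "N = 3")
  expect_error(coarse_grain(c(1, NA, 3), 1), "non-finite")
})

test_that("horizontal visibility follows the strict criterion", {
  expect_equal(edge_set(build_hvg(c(3, 1, 2))), c("1 2", "1 3", "2 3"))
  expect_equal(edge_set(build_hvg(c(1, 3, 2))), c("1 2", "2 3"))
  # strictly monotone series reduce to the path graph
  expect_equal(edge_set(build_hvg(1:5)), c("1 2", "2 3", "3 4", "4 5"))
  expect_equal(edge_set(build_hvg(c(9, 7, 4, 2))), c("1 2", "2 3", "3 4"))
  # ties block: a constant series is also the path graph
  expect_equal(edge_set(build_hvg(rep(2, 4))), c("1 2", "2 3", "3 4"))
  expect_error(build_hvg(5), "too short")
})

test_that("penetrable links tolerate up to L blockers", {
  expect_equal(edge_set(build_lphvg(c(1, 3, 2), L = 1)),
               c("1 2", "1 3", "2 3"))
  # monotone ramp at L = 1: exactly one blocker between i and i+2
  expect_equal(igraph::ecount(build_lphvg(1:5, L = 1)), 7)
  expect_setequal(edge_set(build_lphvg(1:5, L = 1)),
                  c(paste(1:4, 2:5), paste(1:3, 3:5)))
  expect_error(build_lphvg(c(1, 2), L = -1), "L")
})

test_that("the literal reference construction agrees on the worked examples", {
  expect_equal(edge_set(build_lphvg_oracle(c(3, 1, 2), L = 0)),
               c("1 2", "1 3", "2 3"))
  expect_equal(edge_set(build_lphvg_oracle(rep(2, 4), L = 0)),
               c("1 2", "2 3", "3 4"))
})

test_that("L = 0 reduces to the HVG and edge sets grow with L", {
  set.seed(11)
  for (i in 1:20) {
    x <- runif(sample(10:120, 1))
    e0 <- edge_set(build_lphvg(x, L = 0))
    expect_identical(e0, edge_set(build_hvg(x)))
    for (L in 0:2) {
      expect_true(all(edge_set(build_lphvg(x, L)) %in%
                        edge_set(build_lphvg(x, L + 1L))))
    }
  }
})

test_that("edge sets are invariant under positive affine amplitude transforms", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(80)
    for (L in 0:1) {
      e <- edge_set(build_lphvg(x, L))
      expect_identical(edge_set(build_lphvg(x + 17.3, L)), e)
      expect_identical(edge_set(build_lphvg(x * 0.004, L)), e)
      expect_identical(edge_set(build_lphvg(3 * x + 100, L)), e)
    }
  }
})

test_that("every constructed graph is connected with consecutive pairs linked", {
  set.seed(5)
  for (i in 1:10) {
    x <- runif(sample(5:200, 1))
    g <- build_lphvg(x, L = sample(0:2, 1))
    expect_true(igraph::is_connected(g))
    n <- igraph::vcount(g)
    expect_true(all(paste(1:(n - 1), 2:n) %in% edge_set(g)))
    expect_false(igraph::any_multiple(g))
    expect_false(any(igraph::which_loop(g)))
  }
})

test_that("the multiscale family matches per-scale construction", {
  set.seed(9)
  x <- runif(100)
  m <- build_mlphvg(x, scales = c(1, 2, 5), L = 1)
  expect_named(m$graphs, c("1", "2", "5"))
  expect_equal(unname(vapply(m$graphs, igraph::vcount, numeric(1))),
               c(100, 50, 20))
  for (s in c(1L, 2L, 5L)) {
    expect_identical(edge_set(m$graphs[[as.character(s)]]),
                     edge_set(build_lphvg(coarse_grain(x, s), L = 1)))
    expect_equal(igraph::graph_attr(m$graphs[[as.character(s)]], "scale"), s)
  }
  # single-scale family is the plain LPHVG of the raw series
  m1 <- build_mlphvg(x, scales = 1, L = 2)
  expect_identical(edge_set(m1$graphs[["1"]]), edge_set(build_lphvg(x, L = 2)))
  expect_error(build_mlphvg(runif(9), scales = c(1, 5)), "s = 5")
  expect_error(build_mlphvg(x, scales = c(2, 2)), "increasing")
})
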