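# Binomial mismapping model: Pr(X >= x) under Binomial(n, 10^(-m/10)).

direct_tail <- function(n, x, p) {
  # literal complementary summation with exact binomial coefficients
  if (x == 0) return(1)
  if (x > n) return(0)
  k <- 0:(x - 1)
  1 - sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

test_that("tail probability handles the degenerate and reference cases", {
  expect_equal(tail_probability(10, 0, 0.01), 1)
  expect_equal(tail_probability(123, 0, 0.3), 1)
  expect_equal(tail_probability(10, 11, 0.01), 0)
  # depth 30, support 5 at the default threshold p = 0.01; the complementary
  # summation carries ~1e-16 cancellation error, so compare absolutely
  expect_lt(abs(tail_probability(30, 5, 0.01) - direct_tail(30, 5, 0.01)),
            1e-12)
  expect_equal(signif(tail_probability(30, 5, 0.01), 3), 1.16e-5)
  expect_error(tail_probability(10, 2, 1.5), "strictly")
})

test_that("tail probability agrees with the closed form at x = 1", {
  p <- 0.01
  for (n in c(1, 2, 10, 100, 1000)) {
    expect_equal(tail_probability(n, 1, p), 1 - (1 - p)^n, tolerance = 1e-12)
  }
})

test_that("tail + lower tail conserve probability", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:200, 1); x <- sample(0:n, 1)
    lower <- sum(stats::dbinom(0:(x - 1), n, 0.01)) * (x > 0)
    expect_equal(tail_probability(n, x, 0.01) + lower, 1, tolerance = 1e-12)
  }
})

test_that("tables reproduce direct computation and fall through past n_max", {
  tab <- build_tables(20, n_max = 60)
  expect_equal(tab$p, 0.01)
  expect_equal(lookup_tail(tab, 1, 1), 0.01, tolerance = 1e-14)
  set.seed(9)
  n <- sample(1:60, 300, replace = TRUE)
  x <- pmin(n, sample(0:60, 300, replace = TRUE))
  expect_equal(lookup_tail(tab, n, x),
               tail_probability(n, x, 0.01), tolerance = 1e-12)
  # beyond the table: direct computation, same value
  expect_equal(lookup_tail(tab, 200, 3), tail_probability(200, 3, 0.01),
               tolerance = 1e-14)
  # independent cross-check against R's binomial distribution
  expect_equal(lookup_tail(tab, n, x),
               stats::pbinom(x - 1, n, 0.01, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("tables are cached, reloaded, and rebuilt when corrupt", {
  cd <- tempfile("tabcache")
  t1 <- build_tables(25, n_max = 20, cache_dir = cd)
  f <- list.files(cd, full.names = TRUE)
  expect_length(f, 1)
  t2 <- build_tables(25, n_max = 20, cache_dir = cd)
  expect_equal(t1$rows, t2$rows)
  saveRDS(list(garbage = 1), f)
  expect_warning(t3 <- build_tables(25, n_max = 20, cache_dir = cd),
                 "corrupt")
  expect_equal(t3$rows, t1$rows)
})

test_that("p_bc is monotone in support and in depth", {
  tab <- build_tables(20, 120)
  for (n in c(5, 30, 100)) {
    v <- lookup_tail(tab, rep(n, n + 1), 0:n)
    expect_true(all(diff(v) <= 0))       # non-increasing in x
  }
  v <- lookup_tail(tab, 3:100, rep(3, 98))
  expect_true(all(diff(v) >= 0))         # non-decreasing in n at fixed x
})

test_that("cluster scoring rounds fractional support half-up and clamps", {
  expect_identical(round_half_up(c(0.5, 1.4, 1.5, 2.5)), c(1L, 1L, 2L, 3L))
  tab <- build_tables(20, 50)
  cl <- data.frame(support = c(0.5, 3, 10), depth = c(30, 30, 5))
  expect_warning(out <- score_clusters(cl, tab), "clamped")
  expect_equal(out$p_bc[1], tail_probability(30, 1, 0.01))
  expect_equal(out$p_bc[3], tail_probability(5, 5, 0.01))
})
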