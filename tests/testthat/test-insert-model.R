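# Insert-size model: rank-based thresholds at the Phi(+/-3) tail levels
# after removing >5x-median outliers.

test_that("quantile thresholds recover mu +/- 3 sigma on normal inserts", {
  set.seed(101)
  m <- fit_insert_model(rnorm(1e6, 500, 50), read_length = 150)
  expect_gt(m$i_min, 340); expect_lt(m$i_min, 360)
  expect_gt(m$i_max, 640); expect_lt(m$i_max, 660)
  expect_equal(m$i_median, 500, tolerance = 0.01)
})

test_that("5x-median outliers are removed before quantile estimation", {
  sizes <- c(rep(300, 999), 1e5)
  m <- fit_insert_model(sizes, 100)
  expect_equal(m$i_median, 300)
  expect_equal(m$outliers_removed, 1L)
  expect_equal(m$i_max, 300)         # the outlier never reaches the tail
  expect_error(fit_insert_model(numeric(0), 100), "no insert sizes")
})

test_that("a constant library degenerates to a single threshold", {
  m <- fit_insert_model(rep(400, 1e4), 100)
  expect_equal(c(m$i_min, m$i_median, m$i_max), c(400, 400, 400))
})

test_that("fitting is invariant under permutation of the sample", {
  set.seed(5)
  x <- rlnorm(5e4, log(400), 0.2)
  m1 <- fit_insert_model(x, 150)
  m2 <- fit_insert_model(sample(x), 150)
  expect_equal(m1[c("i_min", "i_median", "i_max")],
               m2[c("i_min", "i_median", "i_max")])
})

test_that("tail mass outside [i_min, i_max] converges to Phi(-3)", {
  set.seed(77)
  x <- rexp(1e6, 1 / 300)           # skewed, like real libraries
  m <- fit_insert_model(x, 100)
  kept <- x[x <= 5 * median(x)]
  p <- pnorm(-3)
  se <- sqrt(p * (1 - p) / length(kept))
  expect_lt(abs(mean(kept < m$i_min) - p), 3 * se + 1e-7)
  expect_lt(abs(mean(kept > m$i_max) - p), 3 * se + 1e-7)
})

test_that("pair classification is a total partition with correct labels", {
  m <- insert_model(350, 500, 650, 150)
  pairs <- data.frame(
    chrom1 = "chr1", pos1 = c(1000, 1000, 1000, 1000, 1000, 1000, 1000),
    strand1 = c("+", "+", "+", "+", "-", "+", "+"),
    chrom2 = c(rep("chr1", 5), "chr5", "chr1"),
    pos2 = c(1500, 2000, 1200, 1500, 1500, 800, 1500),
    strand2 = c("-", "-", "-", "+", "+", "-", "-"),
    insert = c(500, 651, 250, 500, 500, NA, 650),
    mate_mapped = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  pairs$insert[is.na(pairs$insert)] <- 0
  cls <- classify_pair(pairs, m)
  expect_equal(as.character(cls),
               c("concordant", "discordant_deletion", "discordant_insertion",
                 "discordant_inversion", "discordant_duplication",
                 "discordant_translocation", "concordant"))
  expect_false(any(is.na(cls)))      # exactly one label per mapped pair
  # unmapped mate dominates everything else
  um <- pairs[1, ]; um$mate_mapped <- FALSE
  expect_equal(as.character(classify_pair(um, m)), "unmapped_mate")
})

test_that("insert sampling honours truncation and the minimum-pair floor", {
  fix <- fixture_sim("flat")
  s <- sample_insert_sizes(fix$bam, max_pairs = 100, min_pairs = 10)
  expect_length(s, 100)
  s2 <- sample_insert_sizes(fix$bam, max_pairs = 1e6, min_pairs = 10)
  expect_lt(abs(median(s2) - 500) / 500, 0.01)
  expect_error(sample_insert_sizes(fix$bam, max_pairs = 1e6,
                                   min_pairs = 1e7),
               "insufficient pairs")
})

test_that("the model round-trips through its JSON sidecar", {
  m <- insert_model(350, 500, 650, 150, n_sampled = 1234L)
  f <- tempfile(fileext = ".json")
  write_insert_model(m, f)
  m2 <- read_insert_model(f)
  expect_equal(m2$i_min, 350); expect_equal(m2$i_max, 650)
  expect_equal(m2$n_sampled, 1234)
})

test_that("bimodal insert libraries trigger the mixed-library warning", {
  set.seed(3)
  expect_warning(check_mixed_library(c(rnorm(5e3, 300, 20),
                                       rnorm(5e3, 900, 20))), "multimodal")
  expect_silent(check_mixed_library(rnorm(1e4, 500, 50)))
})
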