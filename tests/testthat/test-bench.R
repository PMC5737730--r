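# Benchmark harness: reciprocal overlap and truth matching rules.

test_that("reciprocal overlap follows its definition", {
  expect_equal(reciprocal_overlap(0, 100, 0, 100), 1)
  expect_equal(reciprocal_overlap(0, 100, 50, 150), 0.5)
  expect_equal(reciprocal_overlap(0, 100, 200, 300), 0)
  expect_equal(reciprocal_overlap(0, 100, 0, 200), 0.5)   # min of both sides
  expect_error(reciprocal_overlap(5, 5, 0, 10), "zero-length")
})

mkcall <- function(chrom, pos, end, type, len, alt = NA, mate_chrom = NA,
                   mate_pos = NA, support = 10) {
  data.frame(chrom = chrom, pos = pos, end = end, type = type, len = len,
             ref = NA, alt = alt, gt = NA, mate_chrom = mate_chrom,
             mate_pos = mate_pos, support = support, p_bc = 1e-9,
             stringsAsFactors = FALSE)
}

test_that("a truth set evaluated against itself is perfect", {
  truth <- rbind(
    mkcall("chr1", 100, 101, "SNV", 1, alt = "T"),
    mkcall("chr1", 5000, 5010, "DEL", 10),
    mkcall("chr1", 20000, 21000, "DEL", 1000),
    mkcall("chr1", 40000, 45000, "DUP", 5000),
    mkcall("chr1", 60000, 60000, "INS", 120),
    mkcall("chr1", 70000, NA, "TRA", NA, mate_chrom = "chr2",
           mate_pos = 1000))
  ev <- evaluate_calls(truth, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$fp, 0); expect_equal(ev$fn, 0)
})

test_that("indels need 2-base precision, SV insertions 10 bases", {
  truth <- rbind(mkcall("chr1", 5000, 5010, "DEL", 10),
                 mkcall("chr1", 60000, 60000, "INS", 120))
  ok <- rbind(mkcall("chr1", 5002, 5012, "DEL", 10),
              mkcall("chr1", 60009, 60009, "INS", 120))
  expect_equal(evaluate_calls(ok, truth)$sensitivity, 1)
  off <- rbind(mkcall("chr1", 5003, 5013, "DEL", 10),
               mkcall("chr1", 60011, 60011, "INS", 120))
  expect_equal(evaluate_calls(off, truth)$sensitivity, 0)
})

test_that("SVs match by 50% reciprocal overlap, adjustable to 10%", {
  truth <- mkcall("chr1", 20000, 21000, "DEL", 1000)
  half <- mkcall("chr1", 20500, 21500, "DEL", 1000)
  expect_equal(evaluate_calls(half, truth)$sensitivity, 1)   # exactly 0.5
  fifth <- mkcall("chr1", 20800, 21800, "DEL", 1000)
  expect_equal(evaluate_calls(fifth, truth)$sensitivity, 0)
  lowres <- benchmark_rules(reciprocal_overlap = 0.1)
  expect_equal(evaluate_calls(fifth, truth, lowres)$sensitivity, 1)
})

test_that("calls outside the benchmark size range are ignored, not FPs", {
  truth <- rbind(mkcall("chr1", 20000, 21000, "DEL", 1000),
                 mkcall("chr1", 50000, 52000, "DEL", 2000))
  small <- mkcall("chr1", 30000, 30060, "DEL", 60)
  ev <- evaluate_calls(rbind(small, truth), truth)
  expect_equal(ev$fp, 0)
  expect_equal(ev$n_ignored, 1)
  expect_equal(ev$precision, 1)
  # with the clamp off it is an ordinary false positive
  ev2 <- evaluate_calls(rbind(small, truth), truth,
                        benchmark_rules(size_clamp = FALSE))
  expect_equal(ev2$fp, 1)
})

test_that("each truth entry is matched at most once", {
  truth <- mkcall("chr1", 20000, 21000, "DEL", 1000)
  twice <- rbind(mkcall("chr1", 20000, 21000, "DEL", 1000, support = 30),
                 mkcall("chr1", 20010, 21010, "DEL", 1000, support = 10))
  ev <- evaluate_calls(twice, truth)
  expect_equal(ev$tp, 1)
  expect_equal(ev$fp, 1)
})

test_that("disjoint contig naming is a hard error", {
  truth <- mkcall("chr1", 100, 101, "SNV", 1, alt = "T")
  calls <- mkcall("1", 100, 101, "SNV", 1, alt = "T")
  expect_error(evaluate_calls(calls, truth), "contig")
})
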