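# Start/end breakpoint matching and translocation pairing.

model_m <- insert_model(350, 500, 650, 150)   # i_max - i_min = 300

mkcl <- function(chrom, pos, side, type, L, support, p_bc = 1e-10,
                 anchored = TRUE, M = NA_real_, mate_chrom = NA_character_) {
  data.frame(chrom = chrom, pos = pos, side = side, type = type, L_bc = L,
             support = support, n_members = support, anchored = anchored,
             mate_chrom = mate_chrom, M = M, p_bc = p_bc,
             stringsAsFactors = FALSE)
}

test_that("the matching window is (3/8) of the concordant insert range", {
  expect_equal(match_window(model_m), 112.5)
  expect_equal(match_window(insert_model(250, 500, 550, 150)), 112.5)
})

test_that("both residual conditions must hold, at the stated window", {
  # worked residuals: |10000 + 1190 - 11200| = 10, |11200 - 1205 - 10000| = 5
  st <- mkcl("chr1", 10000, "start", "DEL", 1190, 10)
  en <- mkcl("chr1", 11200, "end", "DEL", 1205, 10)
  out <- match_breakpoints(st, en, model_m)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 10000); expect_equal(out$end, 11200)
  # perfectly consistent lengths always match with both residuals zero
  st2 <- mkcl("chr1", 5000, "start", "DUP", 800, 4)
  en2 <- mkcl("chr1", 5800, "end", "DUP", 800, 4)
  expect_equal(nrow(match_breakpoints(st2, en2, model_m)), 1)
  # one residual just past the window: no match
  st3 <- mkcl("chr1", 10000, "start", "DEL", 1200 + 113.5, 10)
  en3 <- mkcl("chr1", 11200, "end", "DEL", 1200, 10)
  expect_equal(nrow(match_breakpoints(st3, en3, model_m)), 0)
})

test_that("greedy matching takes descending support, one use per cluster", {
  st <- rbind(mkcl("chr1", 1000, "start", "DEL", 500, 20),
              mkcl("chr1", 1010, "start", "DEL", 500, 5))
  en <- rbind(mkcl("chr1", 1500, "end", "DEL", 500, 18),
              mkcl("chr1", 1510, "end", "DEL", 500, 4))
  out <- match_breakpoints(st, en, model_m)
  expect_equal(nrow(out), 2)
  best <- out[which.max(out$support), ]
  expect_equal(best$pos, 1000); expect_equal(best$end, 1500)
  expect_equal(sort(out$pos), c(1000, 1010))   # each cluster used once
})

test_that("emitted calls re-satisfy the residual conditions", {
  set.seed(41)
  n <- 30
  st <- mkcl("chr1", sort(sample(1000:50000, n)), "start", "DEL",
             runif(n, 300, 3000), sample(5:40, n, replace = TRUE))
  en <- mkcl("chr1", st$pos + round(st$L_bc + runif(n, -200, 200)), "end",
             "DEL", st$L_bc + runif(n, -150, 150),
             sample(5:40, n, replace = TRUE))
  out <- match_breakpoints(st, en, model_m)
  w <- match_window(model_m)
  if (nrow(out)) {
    for (i in seq_len(nrow(out))) {
      s <- st[st$pos == out$pos[i], ]; e <- en[en$pos == out$end[i], ]
      expect_lte(abs(s$pos + s$L_bc - e$pos), w)
      expect_lte(abs(e$pos - e$L_bc - s$pos), w)
      expect_lt(out$pos[i], out$end[i])
    }
  }
})

test_that("translocation pairing needs both reciprocal conditions", {
  a <- mkcl("chr1", 60000, "start", "TRA", NA, 20, M = 30000,
            mate_chrom = "chr2")
  b <- mkcl("chr2", 30000, "end", "TRA", NA, 18, M = 60000,
            mate_chrom = "chr1")
  out <- match_translocations(rbind(a, b), model_m)
  expect_equal(nrow(out), 1)
  expect_equal(out$chrom, "chr1"); expect_equal(out$mate_pos, 30000)
  # first condition inside the window, second outside: no match
  b2 <- b; b2$M <- 60000 + 113
  expect_equal(nrow(match_translocations(rbind(a, b2), model_m)), 0)
  # three mutually compatible clusters: best-supported pair wins
  a2 <- a; a2$support <- 5; a2$pos <- 60010
  out3 <- match_translocations(rbind(a, a2, b), model_m)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$pos, 60000)
})

test_that("small indels match at base precision and insertions at a locus", {
  st <- mkcl("chr1", 10050, "start", "DEL", 2, 30)
  en <- mkcl("chr1", 10052, "end", "DEL", 2, 30)
  out <- call_small_indels(rbind(st, en), model_m)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 10050); expect_equal(out$end, 10052)
  expect_equal(out$len, 2)
  # an end 3 bases off no longer matches
  en2 <- mkcl("chr1", 10055, "end", "DEL", 2, 30)
  expect_equal(nrow(call_small_indels(rbind(st, en2), model_m)), 0)
  ins <- mkcl("chr1", 7000, "start", "INS", 8, 12)
  out2 <- call_small_indels(ins, model_m)
  expect_equal(out2$type, "INS"); expect_equal(out2$pos, 7000)
  expect_equal(out2$len, 8)
})

test_that("non-maximum suppression keeps the dominant cluster per region", {
  cl <- rbind(
    mkcl("chr1", 1000 + 0:9, "start", "DEL", 1000, c(3, 3, 9, 3, 3, 3, 3, 3, 3, 3)),
    mkcl("chr1", 5000, "start", "DEL", 1000, 4))
  sel <- select_breakpoints(cl, model_m, gap = 300)
  expect_equal(sort(sel$pos), c(1002, 5000))
  # a clearly different length in the same region survives
  cl2 <- rbind(cl, mkcl("chr1", 1003, "start", "DEL", 3000, 5))
  sel2 <- select_breakpoints(cl2, model_m, gap = 300)
  expect_setequal(sel2$pos, c(1002, 1003, 5000))
})
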