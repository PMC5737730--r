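# Single-pass evidence collection: physical depth, breakpoint candidates,
# clip anchoring, SNV mismatch evidence.

model_std <- insert_model(350, 500, 650, 100)   # read length 100 fixtures

test_that("physical depth spans the unsequenced gap of a concordant pair", {
  rec <- c(
    sam_rec("p1", 99, "chr1", 1001, 60, "100M", "=", 1401, 500),
    sam_rec("p1", 147, "chr1", 1401, 60, "100M", "=", 1001, -500))
  bam <- tiny_bam(rec, c(chr1 = 3000))
  sc <- scan_chromosome(bam, "chr1", model_std, strrep("A", 3000))
  d <- as.integer(sc$depth)
  expect_true(all(d[1001:1500] == 1))       # reads + inter-mate gap
  expect_true(all(d[c(1:1000, 1501:3000)] == 0))
  expect_equal(sum(d), 500)                  # exact depth conservation
  expect_equal(nrow(sc$cands), 0)
})

test_that("a discordant deletion pair adds exactly its candidate extents", {
  # insert 1800 = i_median + 1300; windows of width i_max - i_min per side
  rec <- c(
    sam_rec("d1", 97, "chr1", 1001, 60, "100M", "=", 2701, 1800),
    sam_rec("d1", 145, "chr1", 2701, 60, "100M", "=", 1001, -1800))
  bam <- tiny_bam(rec, c(chr1 = 5000))
  sc <- scan_chromosome(bam, "chr1", model_std, strrep("A", 5000))
  expect_equal(sum(as.integer(sc$depth)), 2 * 100 + 2 * 300)
  w <- sc$cands[sc$cands$source == "window", ]
  expect_true(all(w$type == "DEL"))
  expect_equal(unique(w$length), 1800 - 500)        # insert - i_median
  st <- w[w$side == "start", ]; en <- w[w$side == "end", ]
  expect_equal(nrow(st), 300)                        # i_max - i_min
  expect_equal(range(st$pos), c(1100, 1399))         # right of the left read
  expect_equal(range(en$pos), c(2400, 2699))         # left of the right read
})

test_that("an insert at i_max is concordant and yields no candidates", {
  rec <- c(
    sam_rec("b1", 99, "chr1", 1001, 60, "100M", "=", 1551, 650),
    sam_rec("b1", 147, "chr1", 1551, 60, "100M", "=", 1001, -650))
  bam <- tiny_bam(rec, c(chr1 = 4000))
  sc <- scan_chromosome(bam, "chr1", model_std, strrep("A", 4000))
  expect_equal(nrow(sc$cands), 0)
  expect_equal(sum(as.integer(sc$depth)), 650)       # whole fragment
})

test_that("CIGAR indels produce the documented start/end candidates", {
  # a 2-base deletion inside a read starting at 0-based 10,000
  bam <- tiny_bam(sam_rec("r1", 0, "chr1", 10001, 60, "50M2D50M"),
                  c(chr1 = 20000))
  sc <- scan_chromosome(bam, "chr1", model_std, strrep("A", 20000))
  cc <- sc$cands[sc$cands$source == "cigar", ]
  expect_equal(nrow(cc), 2)
  expect_equal(cc$pos[cc$side == "start"], 10050)
  expect_equal(cc$pos[cc$side == "end"], 10052)
  expect_true(all(cc$type == "DEL" & cc$length == 2 & cc$weight == 1))
  # an insertion yields a single candidate at the insertion point
  bam2 <- tiny_bam(sam_rec("r2", 0, "chr1", 5001, 60, "40M6I40M"),
                   c(chr1 = 20000))
  sc2 <- scan_chromosome(bam2, "chr1", model_std, strrep("A", 20000))
  ic <- sc2$cands[sc2$cands$source == "cigar", ]
  expect_equal(nrow(ic), 1)
  expect_equal(ic$pos, 5040)
  expect_true(ic$type == "INS" && ic$length == 6)
})

test_that("short clips and short splits are ignored", {
  rec <- c(
    sam_rec("c1", 0, "chr1", 1001, 60, "4S96M"),      # clip below 5
    sam_rec("c2", 0, "chr1", 2001, 60, "5S95M"))      # qualifying clip
  bam <- tiny_bam(rec, c(chr1 = 10000))
  sc <- scan_chromosome(bam, "chr1", model_std, strrep("A", 10000))
  expect_equal(sc$boundaries, 2000)
  # split with a 15-base mapped segment: no split candidates
  rec2 <- sam_rec("s1", 0, "chr1", 3001, 60, "85M15S",
                  opt = "SA:Z:chr1,5001,+,85S15M,60,0;")
  bam2 <- tiny_bam(rec2, c(chr1 = 10000))
  sc2 <- scan_chromosome(bam2, "chr1", model_std, strrep("A", 10000))
  expect_equal(nrow(sc2$cands[sc2$cands$source == "split", ]), 0)
  # both segments >= 20: a deletion split appears at the inner edges
  rec3 <- sam_rec("s2", 0, "chr1", 3001, 60, "60M40S",
                  opt = "SA:Z:chr1,4001,+,60S40M,60,0;")
  bam3 <- tiny_bam(rec3, c(chr1 = 10000))
  sc3 <- scan_chromosome(bam3, "chr1", model_std, strrep("A", 10000))
  sp <- sc3$cands[sc3$cands$source == "split", ]
  expect_equal(nrow(sp), 2)
  expect_equal(sp$pos[sp$side == "start"], 3060)
  expect_equal(sp$pos[sp$side == "end"], 4000)
  expect_true(all(sp$type == "DEL" & sp$length == 940))
})

test_that("clip anchoring keeps boundary candidates at full weight", {
  cands <- data.frame(
    chrom = "chr1", pos = c(100:104, 200:204), side = "start", type = "DEL",
    length = 1000, weight = 1, read = rep(c("a", "b"), each = 5),
    source = "window", mate_chrom = NA, M = NA_real_,
    window = rep(1:2, each = 5), stringsAsFactors = FALSE)
  # no boundaries: weights unchanged
  expect_equal(apply_clip_anchoring(cands, integer(0))$weight, rep(1, 10))
  # one boundary inside window 1 only
  out <- apply_clip_anchoring(cands, 102)
  expect_equal(out$weight[out$window == 1], c(0.5, 0.5, 1, 0.5, 0.5))
  expect_equal(out$weight[out$window == 2], rep(1, 5))
  # two boundaries in one window: both anchored bases keep full weight
  out2 <- apply_clip_anchoring(cands, c(101, 103))
  expect_equal(out2$weight[out2$window == 1], c(0.5, 1, 0.5, 1, 0.5))
})

test_that("scan rejects unknown chromosomes and unsorted input", {
  fix <- fixture_sim("flat")
  expect_error(scan_chromosome(fix$bam, "chrZ", model_std, "A"), "unknown")
  bam <- tiny_bam(sam_rec("r1", 0, "chr1", 101, 60, "100M"),
                  c(chr1 = 1000), sort_order = "queryname")
  expect_error(scan_chromosome(bam, "chr1", model_std, strrep("A", 1000)),
               "not coordinate-sorted")
})

test_that("mismatch evidence reports position, alleles and qualities", {
  seq <- paste0(strrep("C", 50), "T", strrep("C", 49))
  rec <- paste("m1", 0, "chr1", 1001, 60, "100M", "*", 0, 0, seq,
               strrep("?", 100), sep = "\t")
  bam <- tiny_bam(rec, c(chr1 = 2000))
  sc <- scan_chromosome(bam, "chr1", model_std, strrep("C", 2000))
  expect_equal(nrow(sc$snv), 1)
  expect_equal(sc$snv$pos, 1050)
  expect_equal(sc$snv$ref, "C"); expect_equal(sc$snv$alt, "T")
  expect_equal(sc$snv$count, 1)
  expect_equal(sc$snv$mean_baseq, 30); expect_equal(sc$snv$mean_mapq, 60)
  # the same mismatch inside an indel-bearing read (block-walk path)
  rec2 <- paste("m2", 0, "chr1", 1001, 60, "50M2D50M", "*", 0, 0, seq,
                strrep("?", 100), sep = "\t")
  bam2 <- tiny_bam(rec2, c(chr1 = 2000))
  sc2 <- scan_chromosome(bam2, "chr1", model_std, strrep("C", 2000))
  expect_equal(sc2$snv$pos, 1052)   # 50 M bases, 2 D, then offset 0 of 2nd M
  expect_equal(sc2$snv$alt, "T")
})

test_that("MAPQ 0 reads count toward depth but yield no candidates", {
  rec <- sam_rec("q0", 0, "chr1", 1001, 0, "50M2D50M")
  bam <- tiny_bam(rec, c(chr1 = 3000))
  sc <- scan_chromosome(bam, "chr1", model_std, strrep("A", 3000))
  expect_equal(sum(as.integer(sc$depth)), 102)
  expect_equal(nrow(sc$cands), 0)
})

test_that("empty regions give empty streams", {
  fix <- fixture_sim("flat")
  hdr <- Rsamtools::scanBamHeader(fix$bam)[[1]]
  bam <- tiny_bam(character(0), c(chr1 = 1000))
  sc <- scan_chromosome(bam, "chr1", model_std, strrep("A", 1000))
  expect_equal(nrow(sc$cands), 0)
  expect_equal(nrow(sc$snv), 0)
  expect_equal(sum(as.integer(sc$depth)), 0)
})

test_that("simulated flat coverage matches the fragment-coverage formula", {
  fix <- fixture_sim("flat")
  model <- fixture_model(fix)
  sc <- scan_chromosome(fix$bam, "chr1", model, fixture_ref(fix))
  len <- 60000
  n_frag <- round(fix$spec$coverage / 2 * len / (2 * 150)) * 2
  expected <- n_frag * 500 / len
  expect_lt(abs(mean(sc$depth) - expected) / expected, 0.1)
})

test_that("the top-weight start candidate sits exactly at a planted hom DEL", {
  fix <- fixture_sim("basic")
  model <- fixture_model(fix)
  sc <- scan_chromosome(fix$bam, "chr1", model, fixture_ref(fix))
  st <- sc$cands[sc$cands$type == "DEL" & sc$cands$side == "start" &
                   sc$cands$pos > 30000 & sc$cands$pos < 50000, ]
  support <- tapply(st$weight, st$pos, sum)
  expect_equal(as.integer(names(which.max(support))), 40000)
  # candidate windows never leave the chromosome
  expect_true(all(sc$cands$pos >= 0 & sc$cands$pos <= 100000))
})
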