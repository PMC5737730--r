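# Breakpoint clustering with the adaptive length tolerance.

model_500 <- insert_model(250, 500, 550, 150)   # base term 500

test_that("the tolerance follows the worked example and its limit", {
  expect_equal(cluster_tolerance(model_500, 1), 1000)
  expect_equal(cluster_tolerance(model_500, 1e9), 500, tolerance = 1e-6)
  x <- c(1, 2, 5, 10, 100, 1000)
  expect_true(all(diff(cluster_tolerance(model_500, x)) < 0))
  bad <- insert_model(250, 500, 550, 600)       # base term < 0
  expect_error(cluster_tolerance(bad, 1), "base term")
})

test_that("assignment joins, creates, and prefers the biggest cluster", {
  # singleton creation
  cl <- assign_read(list(), 1700, 1, "r1", model_500)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$L_bc, 1700); expect_equal(cl[[1]]$x_bc, 1)
  # the worked example: second read 500 away joins at tolerance 1000
  cl <- assign_read(cl, 1200, 1, "r2", model_500)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$L_bc, 1450)
  # a well-supported cluster at x=100 rejects a 600-base-away candidate
  big <- list(list(L_bc = 1200, x_bc = 100, ids = paste0("x", 1:100)))
  cl2 <- assign_read(big, 1800, 1, "new", model_500)
  expect_length(cl2, 2)
  expect_equal(cl2[[2]]$L_bc, 1800)
  # biggest eligible cluster wins over a closer small one
  two <- list(list(L_bc = 1000, x_bc = 2, ids = c("a", "b")),
              list(L_bc = 1100, x_bc = 5, ids = paste0("c", 1:5)))
  cl3 <- assign_read(two, 1010, 1, "new", model_500)
  expect_equal(cl3[[2]]$x_bc, 6)
  expect_equal(cl3[[1]]$x_bc, 2)
  # a read never enters the same cluster twice
  cl4 <- assign_read(list(list(L_bc = 1000, x_bc = 1, ids = "dup")),
                     1000, 1, "dup", model_500)
  expect_equal(cl4[[1]]$x_bc, 1)
})

test_that("replaying a cluster's members reproduces it exactly", {
  set.seed(12)
  L <- rnorm(30, 1200, 100); w <- sample(c(0.5, 1), 30, replace = TRUE)
  id <- paste0("r", 1:30)
  cl <- cluster_position(L, w, id, model_500)
  for (c in cl) {
    sel <- match(c$ids, id)
    re <- cluster_position(L[sel], w[sel], id[sel], model_500)
    expect_length(re, 1)
    expect_equal(re[[1]]$L_bc, c$L_bc)
    expect_equal(re[[1]]$x_bc, c$x_bc)
  }
})

test_that("greedy clustering matches an exhaustive oracle on random sets", {
  set.seed(2024)
  base <- cluster_base_term(model_500)
  for (rep in 1:60) {
    n <- sample(1:20, 1)
    L <- round(runif(n, 100, 4000))
    w <- sample(c(0.5, 1), n, replace = TRUE)
    id <- sample(paste0("r", 1:max(2, n %/% 2)), n, replace = TRUE)
    got <- cluster_signature(cluster_position(L, w, id, model_500))
    want <- cluster_signature(oracle_cluster(L, w, id, base))
    expect_equal(got, want)
  }
})

test_that("a dominant cluster recovers the true length from noisy reads", {
  set.seed(31)
  true_len <- 2000
  L <- rnorm(200, true_len, cluster_base_term(model_500) / 4)
  cl <- cluster_position(L, rep(1, 200), paste0("r", 1:200), model_500)
  main <- cl[[which.max(vapply(cl, `[[`, numeric(1), "x_bc"))]]
  expect_gt(main$x_bc, 180)
  se <- cluster_base_term(model_500) / 4 / sqrt(main$x_bc)
  expect_lt(abs(main$L_bc - true_len), 2 * se + 5)
})

test_that("the table-level driver agrees with per-position clustering", {
  set.seed(8)
  n <- 200
  cands <- data.frame(
    chrom = "chr1",
    pos = sample(c(1000, 2000), n, replace = TRUE),
    side = sample(c("start", "end"), n, replace = TRUE),
    type = "DEL",
    length = round(runif(n, 200, 3000)),
    weight = sample(c(0.5, 1), n, replace = TRUE),
    read = paste0("r", 1:n),
    source = sample(c("window", "split"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  out <- cluster_candidates(cands, model_500)
  # recompute every group independently (exact evidence first, as the
  # driver documents)
  for (g in split(seq_len(n), paste(cands$pos, cands$side))) {
    g <- g[order(!(cands$source[g] %in% c("cigar", "split", "clip")), g)]
    want <- cluster_signature(
      oracle_cluster(cands$length[g], cands$weight[g], cands$read[g],
                     cluster_base_term(model_500)))
    sub <- out[out$pos == cands$pos[g[1]] & out$side == cands$side[g[1]], ]
    got <- cluster_signature(lapply(seq_len(nrow(sub)), function(i)
      list(mean = sub$L_bc[i], support = sub$support[i],
           ids = sub$members[[i]])))
    expect_equal(got, want)
  }
  # invariant: L_bc is the weighted mean of member lengths
  for (i in seq_len(nrow(out))) {
    sel <- match(out$members[[i]], cands$read)
    expect_equal(out$L_bc[i],
                 sum(cands$length[sel] * cands$weight[sel]) /
                   sum(cands$weight[sel]))
    expect_false(any(duplicated(out$members[[i]])))
  }
})
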