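test_that("background estimation gives normalized per-position or pooled frequencies", {
  s <- substrate_set("x", rep("DEVDGSAK", 4))
  bg <- estimate_background(s)
  expect_equal(unname(rowSums(bg$frequencies)), rep(1, 8))
  expect_equal(unname(bg$frequencies["P4", "D"]), 1)  # point mass
  two <- substrate_set("y", c("DEVDGSAK", "AKCRWYFH"))
  f <- estimate_background(two)$frequencies
  expect_true(all(f[f > 0] == 0.5))
  pooled <- estimate_background(two, "pooled")
  expect_equal(sum(pooled$frequencies), 1)
  expect_error(estimate_background(substrate_set("t", c("--AKKEAA"))),
               "P4")
  expect_error(estimate_background(substrate_set("e")), "empty")
})

test_that("background simulation is seeded and converges to the model", {
  s <- random_set(50, 4)
  bg <- estimate_background(s)
  sim1 <- simulate_background(bg, 100, seed = 9)
  sim2 <- simulate_background(bg, 100, seed = 9)
  expect_identical(sim1$windows, sim2$windows)
  expect_length(simulate_background(bg, 0, seed = 1)$windows, 0L)
  # point-mass model -> identical windows
  pm <- estimate_background(substrate_set("p", rep("DEVDGSAK", 3)))
  expect_equal(unique(simulate_background(pm, 20, seed = 2)$windows),
               "DEVDGSAK")
  # law of large numbers: per-position chi-square sanity at n = 1e5
  big <- simulate_background(bg, 1e5, seed = 31)
  pfm <- export_pfm(big)
  for (j in c(1, 4, 8)) {
    obs <- pfm[, j]
    p <- bg$frequencies[j, ]
    keep <- p > 0
    expect_gt(stats::chisq.test(obs[keep], p = p[keep])$p.value, 1e-4)
    expect_lt(sum(abs(obs / 1e5 - p)) / 2, 0.01)  # total variation
  }
})

test_that("hypergeometric point probability matches closed forms and normalizes", {
  expect_equal(hypergeom_point_prob(5, 0, 0, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_point_prob(1, 0, 0, 0), 1)
  expect_error(hypergeom_point_prob(0, 0, 0, 0), "n = 0")
  expect_error(hypergeom_point_prob(-1, 2, 3, 4), "non-negative")
  set.seed(12)
  for (i in 1:25) {
    r1 <- sample(0:30, 1); r2 <- sample(0:30, 1)
    if (r1 + r2 == 0) r1 <- 1
    k <- sample(0:(r1 + r2), 1)
    av <- max(0, k - r2):min(r1, k)
    tot <- sum(vapply(av, function(a)
      hypergeom_point_prob(a, r1 - a, k - a, r2 - k + a), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("one-sided Fisher tail matches the enumeration oracle", {
  expect_equal(fisher_exact_greater(5, 0, 0, 5), 1 / 252, tolerance = 1e-14)
  expect_equal(fisher_exact_greater(0, 3, 2, 1), 1)  # a = 0: whole tail
  expect_equal(fisher_exact_greater(2, 3, 2, 3),
               oracle_fisher_greater(2, 3, 2, 3), tolerance = 1e-12)
  # cross-check against stats::fisher.test on random tables
  set.seed(5)
  for (i in 1:20) {
    t <- sample(0:15, 4, TRUE)
    if (sum(t) == 0) t[1] <- 1
    p <- fisher_exact_greater(t[1], t[2], t[3], t[4])
    ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(p, ft, tolerance = 1e-9)
    expect_equal(p, oracle_fisher_greater(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
  }
  # monotone: more overlap at fixed margins -> smaller p
  ps <- vapply(0:5, function(a) fisher_exact_greater(a, 5 - a, 5 - a, a),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("find_prominent flags a strongly planted combination and is reproducible", {
  s <- generate_substrate_set(synthetic_spec(
    200, planted = list(list(kmer = "LK", block = "B2", fraction = 0.6)),
    seed = 1234))
  rec <- find_prominent(s, reps = 200, seed = 42)
  lk <- rec[rec$block == "B2" & rec$kmer == "LK", ]
  expect_true(lk$prominent)
  expect_gte(lk$count, 120L)  # 120 planted, chance matches may add a few
  expect_equal(lk$n_tests, length(unique(substring(
    s$windows[!grepl("-", substring(s$windows, 3, 4))], 3, 4))))
  expect_equal(lk$alpha_corrected, 0.05 / lk$n_tests)
  rec2 <- find_prominent(s, reps = 200, seed = 42)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
  # records sorted by block then descending count
  expect_equal(as.integer(factor(rec$block, levels = unique(rec$block))),
               sort(as.integer(factor(rec$block, levels = unique(rec$block)))))
  b2 <- rec$count[rec$block == "B2"]
  expect_equal(b2, sort(b2, decreasing = TRUE))
})

test_that("a set of identical windows yields no enrichment against itself", {
  s <- substrate_set("const", rep("DEVDGSAK", 30))
  rec <- find_prominent(s, reps = 50, seed = 3)
  expect_equal(nrow(rec), 8L)  # one combination per block
  expect_equal(unique(rec$median_p), 1)
  expect_false(any(rec$prominent))
  expect_equal(unique(rec$votes), 0L)
})

test_that("invalid arguments and empty blocks are handled", {
  s <- random_set(20, 6)
  expect_error(find_prominent(s, reps = 0, seed = 1), "reps")
  expect_error(find_prominent(s, alpha = 1.2, seed = 1), "alpha")
  expect_error(find_prominent(substrate_set("e"), seed = 1), "empty")
  # every window gapped at P4: B4 can receive nothing. Per-position
  # background is then undefined at P4, so use the pooled model.
  trunc <- substrate_set("t", rep(c("--CKKEAA", "--AKKEAA", "-PAKKEAC",
                                    "--GKKEAC"), 5))
  expect_warning(rec <- find_prominent(trunc, reps = 20, seed = 2,
                                       background = "pooled"),
                 "block B4")
  expect_false("B4" %in% rec$block)
  expect_error(find_prominent(trunc, reps = 20, seed = 2), "P4")
})

test_that("coverage fractions bin into the five shades plus a none state", {
  s <- caspase3_fixture()
  rec <- find_prominent(s, reps = 100, seed = 11)
  cov <- substrate_coverage(s, rec)
  expect_equal(cov$block, BLOCK_DEFS$block)
  b4 <- cov[cov$block == "B4", ]
  expect_equal(b4$fraction, 0.6)
  expect_equal(b4$bin, "[0.6,0.8)")
  expect_true(all(cov$bin[cov$n_prominent == 0] == "none"))
  expect_true(all(is.na(cov$fraction[cov$bin == "none"])))
  # boundary binning
  fake <- data.frame(block = "B1", kmer = "D", prominent = TRUE)
  lo <- substrate_set("lo", c(rep("AAADAAAA", 3), rep("AAAKAAAA", 17)))
  expect_equal(substrate_coverage(lo, fake)$bin[4], "[0,0.2)")
  hi <- substrate_set("hi", c(rep("AAADAAAA", 17), rep("AAAKAAAA", 3)))
  expect_equal(substrate_coverage(hi, fake)$bin[4], "[0.8,1]")
})

test_that("cross-protease proportions count proteases with a prominent block", {
  mk <- function(id, blocks) data.frame(
    protease_id = id, block = c("B1", "B2", blocks), kmer = "X",
    prominent = c(FALSE, FALSE, rep(TRUE, length(blocks))))
  res <- list(mk("p1", "B2"), mk("p2", c("B2", "B1")),
              mk("p3", character(0)), mk("p4", "B4'"))
  prop <- protease_block_proportions(res)
  expect_equal(unname(prop[c("B2", "B1", "B4'", "B3")]), c(50, 25, 25, 0))
  all_b1 <- lapply(1:3, function(i) mk(paste0("q", i), "B1"))
  expect_equal(unname(protease_block_proportions(all_b1)["B1"]), 100)
})
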