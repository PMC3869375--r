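test_that("hypergeometric tail matches exact enumeration and phyper in log space", {
  # P(X >= 3) drawing 3 from 6 with 3 marked = 1/20
  expect_equal(10^log10_hypergeom_tail(6, 3, 3, 3), 0.05, tolerance = 1e-12)
  expect_equal(log10_hypergeom_tail(10, 5, 5, 0), 0)
  # exact enumeration agreement for N <= 60
  set.seed(55)
  for (rep in 1:40) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(max(0, n - (N - K)):min(K, n), 1)
    got <- log10_hypergeom_tail(N, K, n, k)
    ora <- oracle_hypergeom_tail(N, K, n, k)
    expect_equal(got, log10(ora), tolerance = 1e-10)
    # margin symmetry
    expect_equal(got, log10_hypergeom_tail(N, n, K, k), tolerance = 1e-10)
  }
  # deep-tail agreement with phyper computed in log space
  expect_equal(log10_hypergeom_tail(14902, 1531, 1302, 588),
               phyper(587, 1531, 14902 - 1531, 1302, lower.tail = FALSE,
                      log.p = TRUE) / log(10),
               tolerance = 1e-9)
  # monotone non-increasing in k
  lp <- vapply(0:20, function(k) log10_hypergeom_tail(60, 30, 20, k), numeric(1))
  expect_true(all(diff(lp) <= 1e-12))
  expect_error(log10_hypergeom_tail(10, 5, 12, 3), "invalid")
})

test_that("binomial tail matches direct summation and pbinom in log space", {
  expect_equal(10^log10_binomial_tail(3, 3, 0.5), 0.125, tolerance = 1e-12)
  expect_equal(log10_binomial_tail(5, 0, 0.3), 0)
  set.seed(56)
  for (rep in 1:30) {
    n <- sample(1:30, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    expect_equal(10^log10_binomial_tail(n, k, p0),
                 oracle_binomial_tail(n, k, p0), tolerance = 1e-10)
  }
  expect_equal(log10_binomial_tail(11948, 9642, 0.43),
               pbinom(9641, 11948, 0.43, lower.tail = FALSE, log.p = TRUE) / log(10),
               tolerance = 1e-9)
  lp <- vapply(0:30, function(k) log10_binomial_tail(30, k, 0.4), numeric(1))
  expect_true(all(diff(lp) <= 1e-12))
  expect_error(log10_binomial_tail(5, 6, 0.5), "invalid")
  expect_error(log10_binomial_tail(5, 2, 1), "p0")
})

test_that("percentages round half-away-from-zero to one decimal", {
  expect_equal(percent(0, 10), 0.0)
  expect_equal(percent(1, 3), 33.3)
  expect_equal(percent(5, 8), 62.5)
  expect_equal(percent(1, 16), 6.3)    # 6.25 rounds away from zero
  expect_error(percent(1, 0), "> 0")
  expect_error(percent(5, 3))
  # complement sums to 100 within rounding
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(1:5000, 1); k <- sample(0:n, 1)
    expect_lt(abs(percent(k, n) + percent(n - k, n) - 100), 0.11)
  }
})

test_that("emergent sets contain exactly the regions new at each time point", {
  s0 <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  s1 <- data.frame(chrom = "chr1", start = c(150L, 500L), end = c(250L, 600L))
  em <- emergent_regions(list(d0 = s0, d2 = s1))
  expect_equal(em$d0, s0)
  expect_equal(em$d2$start, 500L)
  # empty first set -> second set fully emergent
  em2 <- emergent_regions(list(s0[0, ], s1))
  expect_equal(nrow(em2[[2]]), 2)

  set.seed(606)
  for (rep in 1:4) {
    sets <- lapply(1:3, function(i) gen_disjoint_intervals(30, 20000, slot = 200))
    got <- emergent_regions(sets)
    ora <- oracle_emergent(sets)
    for (t in 1:3) expect_equal(got[[t]]$start, ora[[t]]$start)
  }
})

test_that("top-n ranking is by FDR, then score, then coordinate", {
  isl <- data.frame(chrom = "chr1", start = c(300L, 100L, 200L, 400L),
                    end = c(350L, 150L, 250L, 450L),
                    score = c(5, 9, 9, 1),
                    log10_fdr = c(-20, -5, -5, -1))
  top <- top_islands(isl, 3)
  expect_equal(top$start, c(300L, 100L, 200L))
  expect_equal(nrow(top_islands(isl, 10)), 4)
})

test_that("average profiles equal direct per-position counting", {
  centers <- data.frame(chrom = "chr1", center = c(5000L, 9000L))
  # all tags exactly at the centers -> single nonzero central bin
  tl <- tags_from_positions(c(rep(5000, 4), rep(9000, 2)))
  pr <- average_profile(tl, centers, halfwidth = 1000, bin = 5)
  expect_equal(sum(pr$profile > 0), 1)
  expect_equal(which(pr$profile > 0), 201)  # bin covering offset [0,5)
  expect_equal(pr$profile[201], mean(c(4, 2)) * 1e6 / 6)

  # random tags vs a brute-force histogram
  set.seed(21)
  pos <- sample(3000:11000, 400, TRUE)
  tl2 <- tags_from_positions(pos)
  pr2 <- average_profile(tl2, centers, halfwidth = 500, bin = 10)
  brute <- sapply(seq(-500, 490, by = 10), function(off) {
    mean(vapply(centers$center, function(cc) {
      sum(pos >= cc + off & pos < cc + off + 10)
    }, numeric(1)))
  }) * 1e6 / 400
  expect_equal(pr2$profile, brute)

  # uniform tags give a flat profile within sampling error
  set.seed(22)
  tl3 <- tags_from_positions(sample(0:99999, 50000, TRUE))
  pr3 <- average_profile(tl3, data.frame(chrom = "chr1", center = 50000L),
                         halfwidth = 10000, bin = 5)
  expect_lt(stats::sd(pr3$profile) / mean(pr3$profile), 1.2)
})

test_that("heat-map rows rank by central signal and ignore input order", {
  centers <- data.frame(chrom = "chr1", center = c(2000L, 6000L))
  tl <- tags_from_positions(c(rep(6000, 10), 2100))
  hm <- heatmap_matrix(tl, centers, halfwidth = 1000, resolution = 50,
                       rank_window = 400)
  expect_equal(hm$rank_signal, c(10, 1))  # 2100 is inside center 2000's window
  expect_equal(hm$order[1], 2)
  perm <- heatmap_matrix(tl, centers[2:1, , drop = FALSE], halfwidth = 1000,
                         resolution = 50, rank_window = 400)
  expect_equal(perm$matrix, hm$matrix)

  # toy case vs brute-force binning of the first-ranked row
  row1_center <- 6000
  brute <- sapply(seq(-1000, 950, by = 50), function(off) {
    sum(tl$tags$pos >= row1_center + off & tl$tags$pos < row1_center + off + 50)
  }) * 1e6 / tl$total_count
  expect_equal(hm$matrix[1, ], brute)
})

test_that("rank-sum comparisons cover exact, tied and shifted cases", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$less, 0.05, tolerance = 1e-12)
  same <- wilcoxon_rank_sum(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(same$two_sided, 1, tolerance = 1e-9)
  set.seed(88)
  a <- rnorm(50, 1); b <- rnorm(50, 0)
  expect_lt(wilcoxon_rank_sum(a, b)$greater, 1e-3)
  expect_error(wilcoxon_rank_sum(numeric(0), 1))
})
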