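test_that("tag preprocessing removes redundant reads and shifts to fragment midpoints", {
  reads <- data.frame(chrom = "chr1",
                      start = c(1000, 1000, 1000, 2000),
                      end = c(1050, 1050, 1050, 2050),
                      strand = c("+", "+", "+", "-"))
  tl <- preprocess_tags(reads, island_params())
  expect_equal(tl$total_count, 2L)
  # + read at 1000 -> 5' = 1000 -> tag 1075; - read 5' = 2049 -> tag 1974
  expect_setequal(tl$tags$pos, c(1075L, 1974L))

  # mixed-strand toy set against per-read arithmetic
  mix <- data.frame(chrom = "chr1", start = c(100, 300, 550),
                    end = c(150, 350, 600), strand = c("+", "-", "+"))
  got <- sort(preprocess_tags(mix, island_params())$tags$pos)
  expect_equal(got, sort(as.integer(c(100 + 75, 349 - 75, 550 + 75))))

  # redundancy threshold 2 keeps two of three stacked reads
  p2 <- island_params(redundancy_threshold = 2)
  expect_equal(preprocess_tags(reads, p2)$total_count, 3L)
})

test_that("candidate islands realize the window/gap definition on toys", {
  params <- island_params(window_size = 200, gap_windows = 1)
  chrom_lengths <- c(chr1 = 1e6)

  empty <- tag_library(data.frame(chrom = character(0), pos = integer(0),
                                  strand = character(0)))
  expect_equal(nrow(candidate_islands(empty, chrom_lengths, params)), 0)

  # 60 tags in one window on a 1-Mb chromosome: background ~0, one island
  tl <- tags_from_positions(10000 + (1:60))
  isl <- candidate_islands(tl, chrom_lengths, params)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 10000)
  expect_equal(isl$end, 10200)
  expect_equal(isl$chip_count, 60L)

  # eligible windows 2 ineligible windows apart stay separate at g=1,
  # 1 window apart merge
  two_apart <- tags_from_positions(c(10000 + (1:30), 10600 + (1:30)))
  isl2 <- candidate_islands(two_apart, chrom_lengths, params)
  expect_equal(nrow(isl2), 2)
  one_apart <- tags_from_positions(c(10000 + (1:30), 10400 + (1:30)))
  isl3 <- candidate_islands(one_apart, chrom_lengths, params)
  expect_equal(nrow(isl3), 1)
  expect_equal(isl3$end - isl3$start, 600L)
  expect_equal(isl3$chip_count, 60L)
  expect_equal(isl3$n_eligible, 2L)
})

test_that("candidate islands equal the exhaustive window-scan reference on random toys", {
  params <- island_params(window_size = 100, gap_windows = 1, eligibility_p = 0.2)
  chrom_lengths <- c(chr1 = 5e4)
  set.seed(202)
  for (rep in 1:5) {
    # clustered + uniform tags to exercise merging
    ncl <- sample(3:6, 1)
    centers <- sample(1000:49000, ncl)
    pos <- c(unlist(lapply(centers, function(cc) cc + sample(-200:200, 40, TRUE))),
             sample(0:49999, 150, TRUE))
    pos <- pos[pos >= 0 & pos < 5e4]
    tl <- tags_from_positions(pos)
    got <- candidate_islands(tl, chrom_lengths, params)
    ora <- oracle_candidate_islands(tl, chrom_lengths, params)
    expect_equal(got$start, ora$start)
    expect_equal(got$end, ora$end)
    expect_equal(got$chip_count, ora$chip_count)
    expect_equal(got$n_eligible, ora$n_eligible)
    expect_equal(got$score, ora$score, tolerance = 1e-10)
  }
})

test_that("island properties hold: disjoint spans, window-multiple lengths, count floor", {
  params <- island_params(window_size = 100, gap_windows = 2)
  set.seed(301)
  pos <- c(sample(0:49999, 300, TRUE),
           unlist(lapply(sample(2000:48000, 5), function(cc) cc + sample(0:300, 50, TRUE))))
  isl <- candidate_islands(tags_from_positions(pos), c(chr1 = 5e4), params)
  expect_true(nrow(isl) > 0)
  expect_true(all((isl$end - isl$start) %% params$window_size == 0))
  expect_true(all(isl$chip_count >= isl$n_eligible))
  if (nrow(isl) > 1) {
    gaps <- isl$start[-1] - isl$end[-nrow(isl)]
    expect_true(all(gaps > params$gap_windows * params$window_size))
  }
})

test_that("control scoring applies the Poisson/BH contract", {
  params <- island_params(window_size = 200, fdr_threshold = 1e-3)
  chrom_lengths <- c(chr1 = 1e6)
  # enriched chip, sparse uniform control
  set.seed(9)
  chip <- tags_from_positions(c(10000 + (1:100), sample(0:999999, 200, TRUE)))
  ctrl <- tags_from_positions(sample(0:999999, 300, TRUE))
  cand <- candidate_islands(chip, chrom_lengths, params)
  scored <- score_islands_vs_control(cand, chip, ctrl, params)
  big <- scored[scored$start == 10000, ]
  expect_equal(nrow(big), 1)
  # chip_count 100 vs expected ~1 at equal depth: retained even at 1e-15
  p15 <- island_params(window_size = 200, fdr_threshold = 1e-15)
  scored15 <- score_islands_vs_control(cand, chip, ctrl, p15)
  expect_true(any(scored15$start == 10000))
  expect_lt(big$log10_p, -100)
  expect_error(score_islands_vs_control(cand, chip,
                                        tag_library(data.frame(chrom = character(0),
                                                               pos = integer(0),
                                                               strand = character(0))),
                                        params),
               "empty")

  # no enrichment: chip equals its expectation -> p in [0.1, 1], dropped
  flat_cand <- data.frame(chrom = "chr1", start = 0L, end = 200L,
                          chip_count = 5L, n_eligible = 1L, score = 1)
  eq_chip <- tags_from_positions(sample(0:999999, 1000, TRUE))
  eq_ctrl <- tags_from_positions(c(sample(0:999999, 995, TRUE), rep(100L, 5)))
  eq <- score_islands_vs_control(flat_cand, eq_chip, eq_ctrl,
                                 island_params(fdr_threshold = 1e-3))
  expect_equal(nrow(eq), 0)
})

test_that("BH adjustment matches hand-derived step-up values in both scales", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # {1e-20, 0.5, 0.9} at threshold 1e-3 -> exactly one retained
  adj <- bh_adjust(c(1e-20, 0.5, 0.9))
  expect_equal(sum(adj < 1e-3), 1)
  # permutation pairing invariance
  set.seed(77)
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # log10-space step-up agrees with p.adjust where doubles can represent p
  lp <- log10(p)
  expect_equal(10^bh_adjust_log10(lp), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  # and survives magnitudes that underflow linear doubles
  deep <- c(-400, -350, -0.1)
  adj_deep <- bh_adjust_log10(deep)
  expect_equal(adj_deep[1], -400 + log10(3), tolerance = 1e-9)
  expect_true(all(diff(sort(adj_deep)) >= 0))
})

test_that("raising the island FDR threshold only adds islands", {
  chrom_lengths <- c(chr1 = 1e6)
  set.seed(13)
  chip <- tags_from_positions(c(unlist(lapply(sample(10000:900000, 8),
                                              function(cc) cc + sample(0:150, 25, TRUE))),
                               sample(0:999999, 400, TRUE)))
  ctrl <- tags_from_positions(sample(0:999999, 800, TRUE))
  loose <- call_islands(chip, ctrl, chrom_lengths,
                        island_params(window_size = 200, fdr_threshold = 1e-2))
  strict <- call_islands(chip, ctrl, chrom_lengths,
                         island_params(window_size = 200, fdr_threshold = 1e-8))
  key <- function(x) paste(x$chrom, x$start, x$end)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("specificity filter keeps true sites and drops artifacts", {
  isl <- data.frame(chrom = "chr1", start = c(1000L, 5000L), end = c(1400L, 5400L),
                    chip_count = c(200L, 200L), n_eligible = c(2L, 2L),
                    score = c(50, 50))
  # equal depth-normalized counts -> nothing retained
  both <- tags_from_positions(c(1000 + sample(0:399, 200, TRUE),
                                5000 + sample(0:399, 200, TRUE)))
  expect_equal(nrow(specificity_filter(isl, both, both, fdr = 1e-15)), 0)
  # control 200 vs deficient 0 at equal depth -> retained at 1e-15
  ctrl <- tags_from_positions(c(1000 + sample(0:399, 200, TRUE),
                                5000 + sample(0:399, 200, TRUE)))
  ko <- tags_from_positions(c(5000 + sample(0:399, 200, TRUE),
                              sample(600000:999999, 200, TRUE)))
  kept <- specificity_filter(isl, ctrl, ko, fdr = 1e-15)
  expect_equal(kept$start, 1000L)
  expect_lt(kept$log10_p_specific, -15)
})

test_that("specificity filter recovers exactly the planted sites among artifacts", {
  cfg <- small_config()
  ann <- small_annotation()
  p <- island_params(window_size = 50, fdr_threshold = 1e-15)
  chip <- preprocess_tags(simulate_chip_tags(ann, "MLL4", "control"), p)
  ko <- preprocess_tags(simulate_chip_tags(ann, "MLL4", "ko"), p)
  inp <- preprocess_tags(simulate_chip_tags(ann, "INPUT", "control"), p)
  called <- call_islands(chip, inp, cfg$chrom_lengths, p)
  kept <- specificity_filter(called, chip, ko, fdr = 1e-15)
  truth <- ann$elements[ann$elements$has_mll4, c("chrom", "start", "end")]
  artefacts <- ann$elements[ann$elements$is_artifact, c("chrom", "start", "end")]
  # every called island overlapped either a planted or an artifact site;
  # the filter retains the planted set and none of the artifacts
  expect_gt(overlap_partition(kept[, c("chrom", "start", "end")], truth)$n_both / nrow(kept), 0.99)
  expect_equal(overlap_partition(kept[, c("chrom", "start", "end")], artefacts)$n_both, 0)
  expect_gt(overlap_partition(truth, kept[, c("chrom", "start", "end")])$n_both / nrow(truth), 0.95)
})
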