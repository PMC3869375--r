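iv <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end))
}

test_that("element classification applies the four-class rules mutually exclusively", {
  tss <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    tss = c(50000L, 120000L))
  me3 <- iv(49800, 50400)
  k27 <- iv(c(49900, 80100), c(50100, 80500))
  me1 <- iv(c(80000, 140000), c(80600, 140600))
  el <- classify_elements(me1, me3, k27, tss, classifier_params(2500))
  expect_setequal(el$element_class,
                  c("active_promoter", "active_enhancer", "silent_enhancer"))
  ap <- el[el$element_class == "active_promoter", ]
  expect_equal(ap$center, 50000L)
  expect_equal(ap$gene_id, "g1")
  ae <- el[el$element_class == "active_enhancer", ]
  expect_equal(ae$center, 80300L)

  # an H3K4me1 island whose center falls in promoter territory yields no enhancer
  me1_prox <- iv(49900, 50500)
  el2 <- classify_elements(me1_prox, me3, k27, tss, classifier_params(2500))
  expect_false(any(el2$element_class %in% c("active_enhancer", "silent_enhancer")))
  # and an me1 island overlapping me3 yields no enhancer even when distal
  me1_me3 <- iv(200000, 200600)
  me3_far <- rbind(me3, iv(200400, 200900))
  el3 <- classify_elements(me1_me3, me3_far, k27, tss, classifier_params(2500))
  expect_false(any(el3$center == 200300))

  expect_error(classify_elements(me1, me3, k27,
                                 tss[0, , drop = FALSE], classifier_params()),
               "non-empty")
})

test_that("randomized toy classifications equal the rule-by-rule oracle", {
  set.seed(404)
  for (rep in 1:4) {
    tss <- data.frame(gene_id = sprintf("g%02d", 1:8), chrom = "chr1",
                      tss = sort(sample(seq(5000, 195000, by = 400), 8)))
    me1 <- gen_disjoint_intervals(25, 2e5, slot = 2000)
    me3 <- gen_disjoint_intervals(12, 2e5, slot = 2000)
    k27 <- gen_disjoint_intervals(15, 2e5, slot = 2000)
    got <- classify_elements(me1, me3, k27, tss, classifier_params(2500))
    ora <- oracle_classify(me1, me3, k27, tss, 2500)
    expect_equal(got$start, ora$start)
    expect_equal(got$element_class, ora$element_class)
    expect_equal(got$center, ora$center)
  }
})

test_that("peak distribution follows the class priority and conserves counts", {
  elements <- data.frame(
    chrom = "chr1", start = c(1000L, 5000L, 9000L, 13000L),
    end = c(2000L, 6000L, 10000L, 14000L), center = c(1500L, 5500L, 9500L, 13500L),
    element_class = c("active_promoter", "silent_promoter",
                      "active_enhancer", "silent_enhancer"),
    gene_id = NA_character_)
  peaks <- iv(c(1100, 9100, 20000, 900, 5900), c(1200, 9200, 20100, 1100, 9100))
  dist <- distribute_peaks(peaks, elements)
  expect_equal(sum(dist$count), nrow(peaks))
  got <- attr(dist, "assignment")
  expect_equal(got[1], "active_promoter")
  expect_equal(got[2], "active_enhancer")
  expect_equal(got[3], "other")
  # a peak overlapping promoter and enhancer counts once, as a promoter
  expect_equal(got[4], "active_promoter")
  expect_equal(got[5], "silent_promoter")
})

test_that("simulated peak placements produce exact distribution counts", {
  ann <- small_annotation()
  el <- ann$elements
  enh <- el[el$class %in% c("active_enhancer", "silent_enhancer"), , drop = FALSE]
  elements <- data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                         center = enh$center, element_class = enh$class,
                         gene_id = NA_character_)
  # peaks planted dead-center on the first 40 active and 20 silent enhancers
  pa <- enh[enh$class == "active_enhancer", ][1:40, ]
  ps <- enh[enh$class == "silent_enhancer", ][1:20, ]
  peaks <- iv(c(pa$center, ps$center) - 50, c(pa$center, ps$center) + 50)
  dist <- distribute_peaks(peaks, elements)
  expect_equal(dist$count[dist$class == "active_enhancer"], 40L)
  expect_equal(dist$count[dist$class == "silent_enhancer"], 20L)
  expect_equal(dist$count[dist$class == "other"], 0L)
})

test_that("lineage grouping is disjoint, exhaustive and union-based for C/EBP", {
  enh <- data.frame(chrom = "chr1",
                    start = c(1000L, 5000L, 9000L, 13000L),
                    end = c(1600L, 5600L, 9600L, 13600L),
                    center = c(1300L, 5300L, 9300L, 13300L),
                    element_class = "active_enhancer")
  cebpa <- iv(1100, 1200)
  cebpb <- iv(5100, 5200)
  pparg <- iv(c(5150, 9100), c(5250, 9200))
  mll4 <- iv(1100, 1300)
  g <- group_lineage_enhancers(enh, cebpa, cebpb, pparg, mll4)
  expect_equal(g$group, c("CEBP+PPARG-", "CEBP+PPARG+", "CEBP-PPARG+", NA))
  expect_equal(g$has_mll4, c(TRUE, FALSE, FALSE, FALSE))
  bound <- g[!is.na(g$group), ]
  expect_equal(nrow(bound), sum(g$has_cebp | g$has_pparg))

  # planted co-occupancy: group frequencies near the generator probabilities
  ann <- small_annotation()
  cfg <- small_config()
  el <- ann$elements
  act <- el[el$class == "active_enhancer", , drop = FALSE]
  w <- function(flag) iv(el$center[flag] - 50, el$center[flag] + 50)
  g2 <- group_lineage_enhancers(
    data.frame(chrom = act$chrom, start = act$start, end = act$end,
               center = act$center, element_class = act$class),
    w(el$has_cebpa), w(el$has_cebpb), w(el$has_pparg), w(el$has_mll4))
  n <- nrow(g2)
  p_hat <- c(mean(g2$group == "CEBP+PPARG+", na.rm = FALSE),
             mean(g2$group == "CEBP+PPARG-", na.rm = FALSE))
  p_hat[is.na(p_hat)] <- 0
  expect_lt(abs(sum(g2$group == "CEBP+PPARG+", na.rm = TRUE) / n - cfg$p_both),
            3 * sqrt(cfg$p_both * (1 - cfg$p_both) / n))
  expect_lt(abs(sum(!is.na(g2$group)) / n - (cfg$p_cebp + cfg$p_pparg - cfg$p_both)),
            3 * sqrt(0.7 * 0.3 / n))
})

test_that("merge_islands produces the disjoint union", {
  x <- iv(c(0, 50, 200), c(60, 100, 300))
  m <- merge_islands(x)
  expect_equal(m$start, c(0L, 200L))
  expect_equal(m$end, c(100L, 300L))
})
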