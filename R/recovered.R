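# Recovery analysis for ectopically induced enhancers: starting from the
# reference C/EBPbeta+ MLL4+ active enhancers of differentiating cells,
# chain >= 1 bp overlap filters through the overexpression condition
# (C/EBPbeta binding, then MLL4 binding, then H3K4me1 and H3K27ac
# enrichment), split recovered enhancers into premarked vs de novo by
# MLL4 status in vector-control cells, and test knockout dependence of
# H3K4me1 at recovered sites.

#' Recovery filtering chain
#'
#' Sequential set intersections, all by the >= 1 bp overlap rule:
#' reference enhancers -> those with C/EBPbeta binding in the
#' overexpression condition (`n_bound`) -> those also with MLL4 binding
#' (`n_mll4`) -> those additionally overlapping both H3K4me1 and H3K27ac
#' islands (`n_recovered`). Recovered enhancers overlapping an MLL4
#' island from vector-control cells are `premarked`; the rest are
#' `de_novo`.
#'
#' @param reference reference enhancer intervals.
#' @param oe_cebpb,oe_mll4,oe_me1,oe_k27ac filtered island sets from the
#'   overexpression condition.
#' @param vector_mll4 filtered MLL4 islands from vector-control cells.
#' @return list with counts `n_reference`, `n_bound`, `n_mll4`,
#'   `n_recovered`, `n_premarked`, `n_de_novo` and the interval tables
#'   `recovered`, `premarked`, `de_novo`.
#' @export
recovery_chain <- function(reference, oe_cebpb, oe_mll4, oe_me1, oe_k27ac,
                           vector_mll4) {
  reference <- validate_intervals(reference, "reference")
  bound <- reference[overlaps_any(reference, oe_cebpb), , drop = FALSE]
  with_mll4 <- bound[overlaps_any(bound, oe_mll4), , drop = FALSE]
  recovered <- with_mll4[overlaps_any(with_mll4, oe_me1) &
                           overlaps_any(with_mll4, oe_k27ac), , drop = FALSE]
  pre <- overlaps_any(recovered, vector_mll4)
  list(n_reference = nrow(reference), n_bound = nrow(bound),
       n_mll4 = nrow(with_mll4), n_recovered = nrow(recovered),
       n_premarked = sum(pre), n_de_novo = sum(!pre),
       recovered = recovered,
       premarked = recovered[pre, , drop = FALSE],
       de_novo = recovered[!pre, , drop = FALSE])
}

#' Knockout dependence of H3K4me1 at recovered enhancers
#'
#' Per recovered enhancer, tag counts are extracted from the control and
#' deficient H3K4me1 libraries; a one-sided Poisson test asks whether the
#' control count exceeds the depth-scaled deficient count (pseudo-count
#' 1), Benjamini-Hochberg adjusted across enhancers. Returns the
#' fraction of enhancers with a significant decrease.
#'
#' @param recovered recovered enhancer intervals.
#' @param me1_control,me1_deficient `tag_library` objects for the two
#'   genotypes.
#' @param fdr significance threshold (default 1e-3).
#' @return list with `fraction_decreased`, `n`, and the per-enhancer
#'   `log10_fdr` vector.
#' @export
mll4_dependence_of_me1 <- function(recovered, me1_control, me1_deficient,
                                   fdr = 1e-3) {
  stopifnot(inherits(me1_control, "tag_library"),
            inherits(me1_deficient, "tag_library"))
  if (!nrow(recovered)) {
    return(list(fraction_decreased = NA_real_, n = 0L, log10_fdr = numeric(0)))
  }
  ctrl <- count_tags_in_intervals(me1_control, recovered)
  ko <- count_tags_in_intervals(me1_deficient, recovered)
  expected <- pmax(ko, 1) * me1_control$total_count /
    max(me1_deficient$total_count, 1)
  lp <- log10_poisson_tail(ctrl, expected)
  lfdr <- bh_adjust_log10(lp)
  sig <- lfdr < log10(fdr)
  list(fraction_decreased = mean(sig), n = nrow(recovered), log10_fdr = lfdr)
}
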