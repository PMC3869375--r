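# RPKM quantification, fold-change regulation and knockout-dependence
# calls, dependence enrichment, and enhancer-to-gene assignment with
# category resolution.

#' Expression-analysis parameters
#'
#' @param expressed_rpkm RPKM above which a gene counts as expressed
#'   (default 1).
#' @param fc_cutoff fold-change cutoff for up/down regulation and for
#'   knockout dependence; the boundary itself is excluded ("over
#'   2.5-fold").
#' @param pseudo_rpkm pseudo-count added to both terms of every RPKM
#'   ratio, so zero-RPKM denominators stay finite.
#' @return list of class `expression_params`.
#' @export
expression_params <- function(expressed_rpkm = 1, fc_cutoff = 2.5,
                              pseudo_rpkm = 0.1) {
  stopifnot(expressed_rpkm > 0, fc_cutoff > 1, pseudo_rpkm > 0)
  structure(list(expressed_rpkm = expressed_rpkm, fc_cutoff = fc_cutoff,
                 pseudo_rpkm = pseudo_rpkm), class = "expression_params")
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (exonic_length/1000 * mapped_total/1e6)`. Linear in counts,
#' inversely linear in library size.
#'
#' @param count exonic read count (vectorized).
#' @param exonic_length exon-union length in bp (> 0).
#' @param mapped_total total mapped reads in the sample (> 0).
#' @return RPKM values.
#' @export
compute_rpkm <- function(count, exonic_length, mapped_total) {
  if (any(exonic_length <= 0)) stop("exonic_length must be > 0")
  if (any(mapped_total <= 0)) stop("mapped_total must be > 0")
  count / (exonic_length / 1000 * mapped_total / 1e6)
}

#' Count tags on exons
#'
#' A read belongs to a gene when its tag position falls inside the gene's
#' exon union; a tag overlapping several genes counts for each of them.
#'
#' @param tags a `tag_library` of RNA-seq tag positions.
#' @param exons exon table (`gene_id`, `chrom`, `start`, `end`).
#' @return named integer vector of exonic tag counts per gene (all genes
#'   in `exons`, zeros included).
#' @export
count_exonic_tags <- function(tags, exons) {
  genes <- unique(exons$gene_id)
  out <- stats::setNames(integer(length(genes)), genes)
  if (tags$total_count == 0) return(out)
  gr_tags <- GenomicRanges::GRanges(tags$tags$chrom,
                                    IRanges::IRanges(tags$tags$pos + 1L, width = 1L))
  gr_ex <- intervals_to_granges(exons)
  hits <- GenomicRanges::findOverlaps(gr_ex, gr_tags, ignore.strand = TRUE)
  # count each tag once per gene even when it spans two exon rows
  pairs <- unique(data.frame(gene = exons$gene_id[S4Vectors::queryHits(hits)],
                             tag = S4Vectors::subjectHits(hits)))
  tb <- table(pairs$gene)
  out[names(tb)] <- as.integer(tb)
  out
}

ratio_stabilized <- function(num, den, params) {
  (num + params$pseudo_rpkm) / (den + params$pseudo_rpkm)
}

#' Classify regulation between two conditions
#'
#' Fold changes are computed on pseudo-count-stabilized RPKM. A gene is
#' `up` when `after/before` exceeds the cutoff, `down` when
#' `before/after` does, else `unchanged`; the boundary ratio itself is
#' excluded.
#'
#' @param rpkm_before,rpkm_after RPKM vectors.
#' @param params an [expression_params()] object.
#' @return character vector in `up`, `down`, `unchanged`.
#' @export
classify_regulation <- function(rpkm_before, rpkm_after,
                                params = expression_params()) {
  up <- ratio_stabilized(rpkm_after, rpkm_before, params) > params$fc_cutoff
  down <- ratio_stabilized(rpkm_before, rpkm_after, params) > params$fc_cutoff
  ifelse(up, "up", ifelse(down, "down", "unchanged"))
}

#' Classify knockout dependence
#'
#' A gene is dependent when it is down-regulated more than `fc_cutoff`-fold
#' in deficient cells relative to control cells (stabilized ratio
#' `control/deficient > cutoff`).
#'
#' @param rpkm_control,rpkm_deficient RPKM vectors.
#' @param params an [expression_params()] object.
#' @return logical vector, `TRUE` = dependent.
#' @export
classify_dependence <- function(rpkm_control, rpkm_deficient,
                                params = expression_params()) {
  ratio_stabilized(rpkm_control, rpkm_deficient, params) > params$fc_cutoff
}

#' Enrichment of dependent genes among up-regulated genes
#'
#' Hypergeometric enrichment: population = expressed genes, marked =
#' dependent genes, sample = up-regulated genes, observed = their
#' intersection. The p-value is the probability of exceeding the
#' observed overlap by chance, i.e. the strict upper tail `P(X > k)`
#' ([log10_hypergeom_tail()] with `strict = TRUE`), the convention under
#' which the pipeline's reported enrichment statistics are defined.
#'
#' @param expressed,dependent,upregulated character vectors of gene ids;
#'   `dependent` and `upregulated` must be subsets of `expressed`.
#' @return list with `N`, `K`, `n`, `k`, `log10_p`, `p`.
#' @export
dependence_enrichment <- function(expressed, dependent, upregulated) {
  expressed <- unique(expressed)
  dependent <- unique(dependent)
  upregulated <- unique(upregulated)
  if (!all(dependent %in% expressed)) stop("dependent genes must be a subset of expressed genes")
  if (!all(upregulated %in% expressed)) stop("up-regulated genes must be a subset of expressed genes")
  N <- length(expressed); K <- length(dependent)
  n <- length(upregulated); k <- length(intersect(dependent, upregulated))
  lp <- log10_hypergeom_tail(N, K, n, k, strict = TRUE)
  list(N = N, K = K, n = n, k = k, log10_p = lp, p = 10^lp)
}

#' Assign lineage enhancers to genes and resolve gene categories
#'
#' Each enhancer is assigned to the nearest TSS within `max_dist`
#' (default 1,000 kb); distance ties break by lexicographic gene id. Per
#' gene: category is `CEBP+PPARG+` when at least one associated enhancer
#' is; otherwise the group of the nearest associated single-TF enhancer;
#' MLL4 status is positive when any associated enhancer is MLL4+.
#'
#' @param enhancers grouped enhancer table from
#'   [group_lineage_enhancers()] (rows with non-NA `group`), with
#'   `center` and `has_mll4` columns.
#' @param tss TSS table.
#' @param max_dist maximum assignment distance in bp.
#' @return data.frame per assigned gene: `gene_id`, `category`,
#'   `mll4_status`, `n_enhancers`; enhancer-level assignments as
#'   attribute `"assignment"`.
#' @export
assign_enhancers_to_genes <- function(enhancers, tss, max_dist = 1e6) {
  # empty strings arise when grouped tables round-trip through TSV
  enh <- enhancers[!is.na(enhancers$group) & nzchar(enhancers$group), , drop = FALSE]
  if (!nrow(enh)) {
    return(data.frame(gene_id = character(0), category = character(0),
                      mll4_status = character(0), n_enhancers = integer(0)))
  }
  hit <- lapply(seq_len(nrow(enh)), function(i) {
    nearest_tss(enh$chrom[i], enh$center[i], tss, max_dist)
  })
  keep <- !vapply(hit, is.null, logical(1))
  if (!any(keep)) {
    return(data.frame(gene_id = character(0), category = character(0),
                      mll4_status = character(0), n_enhancers = integer(0)))
  }
  amap <- data.frame(enh_row = which(keep),
                     gene_id = vapply(hit[keep], `[[`, character(1), "gene_id"),
                     distance = abs(vapply(hit[keep], `[[`, numeric(1), "distance")),
                     group = enh$group[keep],
                     has_mll4 = enh$has_mll4[keep])
  res <- lapply(split(amap, amap$gene_id), function(g) {
    cat <- if (any(g$group == "CEBP+PPARG+")) {
      "CEBP+PPARG+"
    } else {
      g$group[which.min(g$distance)]
    }
    data.frame(gene_id = g$gene_id[1], category = cat,
               mll4_status = if (any(g$has_mll4)) "MLL4+" else "MLL4-",
               n_enhancers = nrow(g))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "assignment") <- amap
  out
}

#' Summarize fold changes per gene group
#'
#' For each (disjoint) gene group: median and quartiles of log2 fold
#' change, the fraction of induced genes (stabilized fold change above
#' the cutoff), and pairwise rank-sum p-values between groups. Empty
#' groups are dropped with a warning.
#'
#' @param gene_groups named list of gene-id vectors.
#' @param fc_table data.frame with `gene_id` and `log2_fc` (and
#'   optionally `induced`, logical; otherwise derived from
#'   `log2_fc > log2(fc_cutoff)`).
#' @param params an [expression_params()] object.
#' @return list with `summary` (per-group stats) and `pairwise`
#'   (two-sided rank-sum p-value matrix).
#' @export
group_foldchange_summary <- function(gene_groups, fc_table,
                                     params = expression_params()) {
  vals <- lapply(gene_groups, function(g) {
    fc_table[fc_table$gene_id %in% g, , drop = FALSE]
  })
  empty <- !vapply(vals, nrow, integer(1))
  if (any(empty)) {
    warning("dropping empty group(s): ", paste(names(vals)[empty], collapse = ", "))
    vals <- vals[!empty]
  }
  if (!length(vals)) stop("all groups empty")
  summ <- do.call(rbind, lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    q <- stats::quantile(v$log2_fc, c(0.25, 0.5, 0.75), names = FALSE)
    induced <- if ("induced" %in% names(v)) v$induced else v$log2_fc > log2(params$fc_cutoff)
    data.frame(group = nm, n = nrow(v), q1 = q[1], median = q[2], q3 = q[3],
               frac_induced = mean(induced))
  }))
  m <- length(vals)
  pw <- matrix(NA_real_, m, m, dimnames = list(names(vals), names(vals)))
  if (m >= 2) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      p <- wilcoxon_rank_sum(vals[[i]]$log2_fc, vals[[j]]$log2_fc)$two_sided
      pw[i, j] <- pw[j, i] <- p
    }
  }
  list(summary = summ, pairwise = pw)
}
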