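# Four-class chromatin-state classification of regulatory elements from
# H3K4me1 / H3K4me3 / H3K27ac islands, peak-to-class distribution, and
# lineage-enhancer grouping by TF occupancy. The definitions are applied
# mutually exclusively: promoter status is decided first, so an H3K4me1
# island in promoter territory never yields an enhancer.

#' Classifier parameters
#'
#' @param promoter_radius bp around a TSS defining promoter territory.
#'   2.5 kb is the usual distal/proximal cutoff; configurable.
#' @return list of class `classifier_params`.
#' @export
classifier_params <- function(promoter_radius = 2500L) {
  stopifnot(promoter_radius > 0)
  structure(list(promoter_radius = as.integer(promoter_radius)),
            class = "classifier_params")
}

#' Classify regulatory elements
#'
#' Promoters: one element per TSS whose `+/- promoter_radius` window
#' overlaps an H3K4me3 island; active if that window also overlaps an
#' H3K27ac island, else silent. Enhancers: each H3K4me1 island whose
#' center lies more than `promoter_radius` from every TSS and which
#' overlaps no H3K4me3 island; active if it overlaps H3K27ac, else
#' silent. Element centers are the TSS for promoters and the H3K4me1
#' island center for enhancers.
#'
#' @param me1,me3,k27ac island data.frames (each internally
#'   non-overlapping).
#' @param tss TSS table (`gene_id`, `chrom`, `tss`).
#' @param params a [classifier_params()] object.
#' @return data.frame of elements: `chrom`, `start`, `end`, `center`,
#'   `element_class` in `active_promoter`, `silent_promoter`,
#'   `active_enhancer`, `silent_enhancer`, and `gene_id` (promoters only).
#' @export
classify_elements <- function(me1, me3, k27ac, tss,
                              params = classifier_params()) {
  if (is.null(tss) || !nrow(tss)) stop("TSS list must be non-empty")
  for (s in list(me1, me3, k27ac)) {
    if (nrow(s) && has_internal_overlap(validate_intervals(s)))
      stop("island sets must be internally non-overlapping")
  }
  r <- params$promoter_radius
  win <- data.frame(chrom = tss$chrom,
                    start = pmax(0L, tss$tss - r),
                    end = tss$tss + r)
  is_prom <- overlaps_any(win, me3)
  prom_active <- is_prom & overlaps_any(win, k27ac)
  promoters <- data.frame(
    chrom = win$chrom[is_prom], start = win$start[is_prom],
    end = win$end[is_prom], center = tss$tss[is_prom],
    element_class = ifelse(prom_active[is_prom], "active_promoter", "silent_promoter"),
    gene_id = tss$gene_id[is_prom])

  enhancers <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), center = integer(0),
                          element_class = character(0), gene_id = character(0))
  if (nrow(me1)) {
    ctr <- interval_center(me1$start, me1$end)
    dist_ok <- vapply(seq_len(nrow(me1)), function(i) {
      d <- abs(tss$tss[tss$chrom == me1$chrom[i]] - ctr[i])
      !length(d) || min(d) > r
    }, logical(1))
    distal <- dist_ok & !overlaps_any(me1, me3)
    enh_active <- overlaps_any(me1, k27ac)
    if (any(distal)) {
      enhancers <- data.frame(
        chrom = me1$chrom[distal], start = me1$start[distal],
        end = me1$end[distal], center = ctr[distal],
        element_class = ifelse(enh_active[distal], "active_enhancer", "silent_enhancer"),
        gene_id = NA_character_)
    }
  }
  out <- rbind(promoters, enhancers)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

element_class_levels <- c("active_promoter", "silent_promoter",
                          "active_enhancer", "silent_enhancer")

#' Distribute peaks over element classes
#'
#' Assigns each peak to the first element class it overlaps (>= 1 bp) in
#' the priority order active promoter > silent promoter > active
#' enhancer > silent enhancer; peaks overlapping no element fall into
#' `other`. A peak overlapping two classes is counted once, mirroring
#' the mutually exclusive element definitions.
#'
#' @param peaks interval data.frame.
#' @param elements output of [classify_elements()].
#' @return data.frame with `class`, `count`, `percent`, plus the
#'   per-peak assignment as attribute `"assignment"`.
#' @export
distribute_peaks <- function(peaks, elements) {
  peaks <- validate_intervals(peaks, "peaks")
  assign <- rep("other", nrow(peaks))
  for (cl in rev(element_class_levels)) {
    el <- elements[elements$element_class == cl, , drop = FALSE]
    hit <- overlaps_any(peaks, el)
    assign[hit] <- cl
  }
  counts <- vapply(c(element_class_levels, "other"),
                   function(cl) sum(assign == cl), integer(1))
  out <- data.frame(class = names(counts), count = as.integer(counts),
                    percent = if (nrow(peaks)) percent(as.integer(counts), nrow(peaks)) else NA_real_)
  attr(out, "assignment") <- assign
  out
}

#' Group lineage enhancers by TF occupancy
#'
#' C/EBP is the merged union of the C/EBPalpha and C/EBPbeta island sets
#' (the two factors bind near-identical motifs). Each active enhancer
#' joins a group by >= 1 bp overlap: `CEBP+PPARG+` (both), `CEBP+PPARG-`,
#' or `CEBP-PPARG+`; enhancers bound by neither are excluded. Groups are
#' disjoint and exhaustive over the TF-bound active enhancers. An MLL4
#' occupancy flag is set per enhancer when `mll4` islands are supplied.
#'
#' For the myogenic analog pass the MyoD islands as `cebpa` with
#' `cebpb = NULL, pparg = NULL`; the single-TF group is then `CEBP+PPARG-`
#' (read: TF-bound).
#'
#' @param active_enhancers element table rows with
#'   `element_class == "active_enhancer"`.
#' @param cebpa,cebpb,pparg,mll4 island data.frames (`NULL` for absent).
#' @return the enhancer table with logical `has_cebp`, `has_pparg`,
#'   `has_mll4` and a `group` column (NA for unbound enhancers).
#' @export
group_lineage_enhancers <- function(active_enhancers, cebpa, cebpb = NULL,
                                    pparg = NULL, mll4 = NULL) {
  enh <- active_enhancers
  cebp <- merge_islands(rbind_intervals(cebpa, cebpb))
  enh$has_cebp <- overlaps_any(enh, cebp)
  enh$has_pparg <- if (is.null(pparg)) rep(FALSE, nrow(enh)) else overlaps_any(enh, pparg)
  enh$has_mll4 <- if (is.null(mll4)) rep(FALSE, nrow(enh)) else overlaps_any(enh, mll4)
  enh$group <- ifelse(enh$has_cebp & enh$has_pparg, "CEBP+PPARG+",
               ifelse(enh$has_cebp, "CEBP+PPARG-",
               ifelse(enh$has_pparg, "CEBP-PPARG+", NA_character_)))
  enh
}

# stack interval tables that may be NULL/empty, keeping core columns
rbind_intervals <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x), list(...))
  if (!length(parts)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  do.call(rbind, lapply(parts, function(x) x[, c("chrom", "start", "end"), drop = FALSE]))
}

#' Merge overlapping intervals into their union
#'
#' @param x interval data.frame.
#' @return non-overlapping merged intervals.
#' @export
merge_islands <- function(x) {
  if (!nrow(x)) return(x)
  gr <- IRanges::reduce(intervals_to_granges(x), ignore.strand = TRUE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}
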