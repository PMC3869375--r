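#!/usr/bin/env Rscript
# Step 4 — TF co-localization on active enhancers.
#
# Groups active enhancers by adipogenic TF occupancy (C/EBP = merged
# union of C/EBPalpha and C/EBPbeta islands; PPARgamma separate), flags
# MLL4 co-occupancy, tests whether MLL4 is preferentially found on
# TF-bound active enhancers (hypergeometric), and exports the ranked
# heat-map matrix of MLL4 signal around grouped enhancer centers.

suppressMessages(library(enhancerIslands))

isl <- function(f) data.table::fread(file.path("results/islands", f), data.table = FALSE)
elements <- data.table::fread("results/elements.tsv", data.table = FALSE)
ae <- elements[elements$element_class == "active_enhancer", ]
mll4 <- isl("mll4_filtered.tsv")

grouped <- group_lineage_enhancers(ae, isl("cebpa.tsv"), isl("cebpb.tsv"),
                                   isl("pparg.tsv"), mll4)
data.table::fwrite(grouped, "results/lineage_enhancers.tsv", sep = "\t", quote = FALSE)
message("lineage enhancer groups:")
print(table(grouped$group, useNA = "ifany"))
for (g in sort(unique(stats::na.omit(grouped$group)))) {
  sel <- grouped$group %in% g
  message(sprintf("  %s: %d enhancers, %.1f%% MLL4+", g, sum(sel),
                  percent(sum(grouped$has_mll4[sel]), sum(sel))))
}

# is MLL4 enriched on TF-bound active enhancers relative to all active
# enhancers? population = active enhancers, marked = MLL4+, sample = TF-bound
N <- nrow(grouped)
K <- sum(grouped$has_mll4)
bound <- !is.na(grouped$group)
n <- sum(bound)
k <- sum(grouped$has_mll4 & bound)
lp <- log10_hypergeom_tail(N, K, n, k)
message(sprintf("MLL4 on TF-bound active enhancers: %d/%d (%.1f%%) vs %d/%d (%.1f%%) overall; log10 p = %.1f",
                k, n, percent(k, n), K, N, percent(K, N), lp))

# Venn-style bookkeeping of C/EBP vs PPARgamma binding regions
cebp <- merge_islands(rbind(isl("cebpa.tsv")[, c("chrom", "start", "end")],
                            isl("cebpb.tsv")[, c("chrom", "start", "end")]))
ov <- overlap_partition(cebp, isl("pparg.tsv")[, c("chrom", "start", "end")])
message(sprintf("C/EBP vs PPARgamma regions: %d shared, %d C/EBP-only, %d PPARgamma-only",
                ov$n_both, ov$n_a_only, ov$n_b_only))

# ranked heat-map matrix of MLL4 signal on double-positive enhancers
tags <- preprocess_tags(read_bed("results/fixtures/reads_mll4_control.bed"),
                        island_params(window_size = 50))
dp <- grouped[grouped$group %in% "CEBP+PPARG+", ]
hm <- heatmap_matrix(tags, data.frame(chrom = dp$chrom, center = dp$center))
utils::write.table(hm$matrix, "results/mll4_heatmap_double_positive.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
message("heat map: ", nrow(hm$matrix), " rows ranked by central MLL4 intensity")
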