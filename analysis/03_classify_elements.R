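#!/usr/bin/env Rscript
# Step 3 — chromatin-state classification of regulatory elements.
#
# Four mutually exclusive classes from H3K4me1/H3K4me3/H3K27ac islands
# and the TSS annotation (promoter territory +/- 2.5 kb), then the
# genomic distribution of filtered MLL4 peaks over those classes and the
# binomial test of MLL4 concentration on active enhancers, with the
# active-enhancer length fraction as the background success probability.

suppressMessages(library(enhancerIslands))

isl <- function(f) data.table::fread(file.path("results/islands", f), data.table = FALSE)
anno <- read_annotation("results/fixtures/annotation.tsv")

elements <- classify_elements(isl("me1.tsv"), isl("me3.tsv"), isl("k27ac.tsv"),
                              anno$tss, classifier_params(2500))
data.table::fwrite(elements, "results/elements.tsv", sep = "\t", quote = FALSE)
print(table(elements$element_class))

mll4 <- isl("mll4_filtered.tsv")
dist <- distribute_peaks(mll4[, c("chrom", "start", "end")], elements)
data.table::fwrite(dist, "results/mll4_distribution.tsv", sep = "\t", quote = FALSE)
message("MLL4 peak distribution over element classes:")
print(dist)

el_len <- tapply(elements$end - elements$start, elements$element_class, sum)
p0 <- unname(el_len["active_enhancer"] / sum(el_len))
on_el <- sum(dist$count[dist$class != "other"])
k_ae <- dist$count[dist$class == "active_enhancer"]
lp <- log10_binomial_tail(on_el, k_ae, p0)
message(sprintf("active enhancers are %.1f%% of element length; %d of %d MLL4 peaks (%.1f%%) lie on them",
                100 * p0, k_ae, on_el, percent(k_ae, on_el)))
message(sprintf("binomial test of MLL4 concentration on active enhancers: log10 p = %.1f", lp))

# signal profile of MLL4 around active-enhancer centers (5-bp bins, +/-10 kb)
ae <- elements[elements$element_class == "active_enhancer", ]
tags <- preprocess_tags(read_bed("results/fixtures/reads_mll4_control.bed"),
                        island_params(window_size = 50))
pr <- average_profile(tags, data.frame(chrom = ae$chrom, center = ae$center))
data.table::fwrite(data.frame(offset = pr$offset, rpm = pr$profile),
                   "results/mll4_profile_active_enhancers.tsv", sep = "\t", quote = FALSE)
message("profile peak/flank ratio: ",
        round(max(pr$profile) / (mean(pr$profile[1:100]) + 1e-9), 1))
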