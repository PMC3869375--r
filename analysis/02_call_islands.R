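#!/usr/bin/env Rscript
# Step 2 — island calling and the knockout specificity filter.
#
# Histone marks: 200-bp windows, island FDR < 1e-3 vs input. MLL4 and
# TFs: 50-bp windows, FDR < 1e-15 vs input. MLL4 islands are then kept
# only where enrichment is significantly higher in control than in
# MLL4-deficient cells (FDR < 1e-15), which removes the planted
# antibody-artifact sites.

suppressMessages(library(enhancerIslands))

fix <- "results/fixtures"
out <- "results/islands"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
chrom_lengths <- c(chr1 = 1e7)

histone <- island_params(window_size = 200, fdr_threshold = 1e-3)
factor <- island_params(window_size = 50, fdr_threshold = 1e-15)
roles <- list(me1 = histone, me3 = histone, k27ac = histone,
              mll4_control = factor, cebpa = factor, cebpb = factor,
              pparg = factor)

input <- preprocess_tags(read_bed(file.path(fix, "reads_input.bed")), factor)
libs <- list()
for (role in names(roles)) {
  libs[[role]] <- preprocess_tags(read_bed(file.path(fix, paste0("reads_", role, ".bed"))),
                                  roles[[role]])
  isl <- call_islands(libs[[role]], input, chrom_lengths, roles[[role]])
  write_islands(isl, file.path(out, paste0(role, ".bed")),
                file.path(out, paste0(role, ".tsv")))
  message(role, ": ", nrow(isl), " islands (W=", roles[[role]]$window_size,
          ", FDR<", roles[[role]]$fdr_threshold, ")")
}

mll4_ko <- preprocess_tags(read_bed(file.path(fix, "reads_mll4_ko.bed")), factor)
mll4_raw <- data.table::fread(file.path(out, "mll4_control.tsv"), data.table = FALSE)
mll4 <- specificity_filter(mll4_raw, libs$mll4_control, mll4_ko, fdr = 1e-15)
write_islands(mll4, file.path(out, "mll4_filtered.bed"),
              file.path(out, "mll4_filtered.tsv"))
message("MLL4 after specificity filter: ", nrow(mll4), " of ", nrow(mll4_raw),
        " islands retained")

truth <- data.table::fread(file.path(fix, "truth_elements.tsv"), data.table = FALSE)
planted <- truth[truth$has_mll4, c("chrom", "start", "end")]
prec <- overlap_partition(mll4[, c("chrom", "start", "end")], planted)$n_both / nrow(mll4)
rec <- overlap_partition(planted, mll4[, c("chrom", "start", "end")])$n_both / nrow(planted)
message(sprintf("recovery of planted MLL4 sites: precision %.3f, recall %.3f",
                prec, rec))

# browser-ready depth-normalized coverage for the MLL4 library
write_bedgraph(coverage_track(libs$mll4_control, bin = 50),
               file.path(out, "mll4_control_coverage.bedgraph"), "MLL4_control")
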