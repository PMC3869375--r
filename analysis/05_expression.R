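#!/usr/bin/env Rscript
# Step 5 — expression regulation, knockout dependence, and
# enhancer-to-gene assignment.
#
# RPKM from exonic counts; up/down calls between day 0 and day 2 (fold
# change > 2.5); knockout-dependent genes (> 2.5-fold down in deficient
# vs control cells at day 2); hypergeometric enrichment of dependent
# genes among up-regulated genes; then nearest-TSS assignment of grouped
# enhancers to genes (<= 1,000 kb) with category resolution and per-group
# fold-change box-plot summaries.

suppressMessages(library(enhancerIslands))

counts <- data.table::fread("results/fixtures/expression_counts.tsv", data.table = FALSE)
anno <- read_annotation("results/fixtures/annotation.tsv")
len <- exonic_lengths(anno$exons)[counts$gene_id]
samples <- c("ctrl_D0", "ctrl_D2", "ko_D0", "ko_D2")
rpkm <- sapply(samples, function(s) compute_rpkm(counts[[s]], len, sum(counts[[s]])))
rownames(rpkm) <- counts$gene_id

ep <- expression_params()
expressed <- counts$gene_id[rpkm[, "ctrl_D0"] > 1 | rpkm[, "ctrl_D2"] > 1]
reg <- classify_regulation(rpkm[expressed, "ctrl_D0"], rpkm[expressed, "ctrl_D2"], ep)
dep <- classify_dependence(rpkm[expressed, "ctrl_D2"], rpkm[expressed, "ko_D2"], ep)
upregulated <- expressed[reg == "up"]
dependent <- expressed[dep]
enr <- dependence_enrichment(expressed, dependent, upregulated)
message(sprintf("expressed %d; up-regulated %d; knockout-dependent %d; overlap %d",
                enr$N, enr$n, enr$K, enr$k))
message(sprintf("dependence enrichment among up-regulated genes: log10 p = %.2f", enr$log10_p))

truth <- data.table::fread("results/fixtures/truth_genes.tsv", data.table = FALSE)
planted <- truth$gene_id[truth$planted_dependent]
message(sprintf("dependent-gene recovery: precision %.3f, recall %.3f",
                mean(dependent %in% planted), mean(planted %in% dependent)))

expr_out <- data.frame(gene_id = counts$gene_id, counts[, samples], rpkm = rpkm,
                       regulation = ifelse(counts$gene_id %in% expressed,
                                           reg[match(counts$gene_id, expressed)], NA),
                       dependent = counts$gene_id %in% dependent)
data.table::fwrite(expr_out, "results/expression.tsv", sep = "\t", quote = FALSE)

# enhancer-to-gene categories and fold-change summaries
grouped <- data.table::fread("results/lineage_enhancers.tsv", data.table = FALSE)
assigned <- assign_enhancers_to_genes(grouped, anno$tss, max_dist = 1e6)
data.table::fwrite(assigned, "results/gene_categories.tsv", sep = "\t", quote = FALSE)
message("gene categories:")
print(table(assigned$category, assigned$mll4_status))

fc_table <- data.frame(
  gene_id = expressed,
  log2_fc = log2((rpkm[expressed, "ko_D2"] + ep$pseudo_rpkm) /
                   (rpkm[expressed, "ctrl_D2"] + ep$pseudo_rpkm)),
  induced = reg == "up")
groups <- split(assigned$gene_id, paste0(assigned$category, "/", assigned$mll4_status))
fc <- suppressWarnings(group_foldchange_summary(groups, fc_table, ep))
data.table::fwrite(fc$summary, "results/category_foldchange.tsv", sep = "\t", quote = FALSE)
message("per-category knockout log2 fold change (day 2) and induced fraction:")
print(fc$summary)
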