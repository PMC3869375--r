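#!/usr/bin/env Rscript
# Step 1 — generate the simulated study dataset.
#
# One 10-Mb chromosome with 500 genes and 600 enhancers; ChIP read
# libraries (200k tags, 50-fold peak enrichment) for MLL4 (control +
# knockout), input, H3K4me1/3, H3K27ac and the three adipogenic TFs;
# per-gene exonic counts for control/knockout at day 0 and day 2. Ground
# truth goes to results/fixtures/truth_*.tsv.

suppressMessages(library(enhancerIslands))

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 42L)
ds <- simulate_dataset(cfg, "results/fixtures")

el <- ds$annotation$elements
message("elements: ", sum(el$class == "active_enhancer"), " active enhancers, ",
        sum(el$class == "silent_enhancer"), " silent enhancers, ",
        sum(el$is_artifact), " MLL4 antibody-artifact sites")
message("planted MLL4+ sites: ", sum(el$has_mll4))
message("planted knockout-dependent genes: ", length(ds$expression$truth))
message("fixtures written under results/fixtures/")
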