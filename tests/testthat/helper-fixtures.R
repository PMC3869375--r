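# Shared simulated fixtures, built once per test run. The default
# dataset uses the standard study conditions (seed 42); the small
# dataset keeps unit tests fast.

.fixtures <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixtures$default)) {
    dir <- file.path(tempdir(), "eisl_default_fixture")
    .fixtures$default <- simulate_dataset(sim_config(seed = 42L), dir)
    .fixtures$default_dir <- dir
  }
  .fixtures$default
}

default_dataset_dir <- function() {
  default_dataset()
  .fixtures$default_dir
}

small_config <- function(seed = 7L, tags_per_library = 5e4, ...) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 2e6),
             n_genes = 100L, n_active_promoters = 60L, n_silent_promoters = 30L,
             n_active_enhancers = 80L, n_silent_enhancers = 40L,
             n_artifact_sites = 15L, tags_per_library = tags_per_library, ...)
}

small_annotation <- function() {
  if (is.null(.fixtures$small_ann)) {
    .fixtures$small_ann <- simulate_annotation(small_config())
  }
  .fixtures$small_ann
}
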