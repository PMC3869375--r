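.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", "count", "win", "chrom", "pos", "strand", "island",
  "first_win", "last_win", "n_eligible", "score", "start", "end",
  "five_prime", "idx", "b", "chip_count"
))
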