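.datatable.aware <- TRUE

# symbols used inside data.table expressions
utils::globalVariables(c(
  "q", "is_dmc", "chrom", "pos", "stage2_q", "stage", "anchor",
  "dmr", "gene", "mu_a", "mu_b", "testable", "idx", "w", "lab", "p"))
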