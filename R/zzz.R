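.datatable.aware <- TRUE

## data.table / NSE symbols used inside `[` expressions
utils::globalVariables(c(
    ".", ":=", ".N", "read_id", "allele", "hap1", "hap2", "is1", "is2",
    "n_hap1", "n_hap2", "bit", "vid", "v1", "v2", "cis", "w"))
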