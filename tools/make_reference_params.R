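# Regenerates the packaged plain-text parameter table of the synthetic
# reference instance from the in-code builder.
# Usage: Rscript tools/make_reference_params.R
library(colikin)
write_parameter_table(ecoli_reference_model(compile = FALSE),
                      "inst/extdata/ecoli_synthetic_params.tsv")
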