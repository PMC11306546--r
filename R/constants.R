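# the five overhead expenditure categories, in canonical order
OVERHEAD_COMPONENTS <- c("equipment", "software", "transportation", "space", "benefits")
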