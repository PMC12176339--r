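quantity,value_brl
per_case_point,1312.74
per_case_ci_low,498.34
per_case_ci_high,2089.24
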