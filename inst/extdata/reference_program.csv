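year,nt_count_all,nt_count_hiae,direct_cost_hiae_brl
2020,11441,5169,3540540.93
2021,38427,7923,3168536.18
2022,35010,7632,3518224.48
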