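# Annual stratum transition probabilities, female hierarchy (published values)
p_hh = 0.9184
p_hl = 0.0816
p_lh = 0.1985
p_ll = 0.8015
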