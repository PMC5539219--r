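# Annual stratum transition probabilities, male hierarchy (published values)
p_hh = 0.9570
p_hl = 0.0430
p_lh = 0.1854
p_ll = 0.8146
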