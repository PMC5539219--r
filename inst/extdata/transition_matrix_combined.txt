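# Annual stratum transition probabilities, sexes combined (published values)
p_hh = 0.9375
p_hl = 0.0625
p_lh = 0.1922
p_ll = 0.8078
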