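year,individual_id,sex,rank
1,A,M,1
1,B,M,2
1,C,M,3
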