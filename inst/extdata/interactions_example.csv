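year,actor_id,recipient_id,winner_id
1,A,B,A
1,A,B,A
1,A,B,A
1,A,B,A
1,A,B,A
1,B,C,B
1,B,C,B
1,B,C,B
1,B,C,B
1,C,A,C
1,C,A,C
1,C,A,C
1,A,C,A
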