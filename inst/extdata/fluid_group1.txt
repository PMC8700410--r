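# Insulating fluid breakdown times under high voltage stress, minutes
# (Nelson, 1982), group 1 (strength sample).
0.31
0.66
1.54
1.70
1.82
1.89
2.17
2.24
4.03
9.99
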