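# Insulating fluid breakdown times under high voltage stress, minutes
# (Nelson, 1982), group 2 (stress sample).
0.49
0.64
0.82
0.93
1.08
1.99
2.06
2.15
2.57
4.75
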