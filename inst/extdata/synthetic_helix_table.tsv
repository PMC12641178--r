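helix_id	molecule	fp_start	fp_end	tp_start	tp_end
H76	23S	10	21	30	41
H77	23S	50	58	65	73
H78	23S	90	99	110	119
H58	23S	140	151	160	171
H12	23S	190	199	210	219
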