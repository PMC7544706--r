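method	day	shrinkage_percent
conventional	0.125	22.1
conventional	3	31.9
conventional	6	32.1
conventional	75	49.4
agar	0.125	2.6
agar	3	32.2
agar	6	40.5
agar	75	67.4
metal	0.125	3.9
metal	6	8.4
metal	75	16.3
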