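projection	metal	conventional	n
xy	0.85	0.80	8
yz	0.62	0.41	8
3d	1.25	1.05	8
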