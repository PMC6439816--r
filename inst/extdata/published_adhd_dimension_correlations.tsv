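domain	dimension	r_ph	r_g
ADHD	dimension_a	0.45	0.49
ADHD	dimension_b	0.53	0.57
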