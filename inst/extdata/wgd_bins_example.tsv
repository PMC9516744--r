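label	lo	hi	mya
alpha	0.4	1.1	50
beta	1.1	2.2	75
lambda	2.2	3.5	150
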