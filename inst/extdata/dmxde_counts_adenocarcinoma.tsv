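compartment	category	n
PR	HyperDown	64
PR	HypoUp	16
PR	other	1239
GB	HyperUp	138
GB	HypoDown	2998
GB	other	32601
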