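compartment	category	n
PR	HyperDown	75
PR	HypoUp	38
PR	other	3113
GB	HyperUp	219
GB	HypoDown	3753
GB	other	71542
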