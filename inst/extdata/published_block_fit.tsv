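intercept	slope
1.04	0.039
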