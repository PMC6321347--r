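2
hydrogen molecule
H    0.000000  0.000000  0.000000
H    0.740000  0.000000  0.000000
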