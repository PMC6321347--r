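4
formaldehyde, near-equilibrium
C    0.000000  0.000000  0.000000
O    0.000000  1.210000  0.000000
H    0.940000 -0.540000  0.000000
H   -0.940000 -0.540000  0.000000
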