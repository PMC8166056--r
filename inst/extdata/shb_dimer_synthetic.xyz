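9
hb_length=2.45
C       1.20000000      0.00000000      0.00000000
C       0.37082039      1.14126782      0.00000000
C      -0.97082039      0.70534230      0.00000000
C      -0.97082039     -0.70534230      0.02500000
N       0.37082039     -1.14126782      0.00000000
O       0.75207011      2.31463380      0.00000000
O       6.00000000     -1.22500000      0.00000000
H       6.00000000     -0.17500000      0.00000000
O       6.00000000      1.22500000      0.00000000
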