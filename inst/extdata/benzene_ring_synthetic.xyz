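12
synthetic benzene-like ring geometry (angstrom); standard bond lengths, not an optimized structure
C   1.391000   0.000000   0.000000
C   0.695500   1.204584   0.000000
C  -0.695500   1.204584   0.000000
C  -1.391000   0.000000   0.000000
C  -0.695500  -1.204584   0.000000
C   0.695500  -1.204584   0.000000
H   2.475000   0.000000   0.000000
H   1.237500   2.143470   0.000000
H  -1.237500   2.143470   0.000000
H  -2.475000   0.000000   0.000000
H  -1.237500  -2.143470   0.000000
H   1.237500  -2.143470   0.000000
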