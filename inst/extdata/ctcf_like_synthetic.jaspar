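>CTCF_SYNTH synthetic CTCF-like test matrix (not the JASPAR MA0139.1 profile)
A [  20   5   5 150  10   5 160   5  10   5   5  20  10   5  30 ]
C [ 140 160  10  10 150   5  10   5  10 150 140  20  10 150  40 ]
G [  20  20 160  20  20 170  10 180 160  25  20 140 170  20  60 ]
T [  20  15  25  20  20  20  20  10  20  20  35  20  10  25  70 ]
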