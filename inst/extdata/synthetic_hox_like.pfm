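>synthetic_hox_like posterior-Hox-like synthetic matrix, consensus TTTATGGC
A [  2  3  4 85  5  3  6  4 ]
C [  3  2  3  4  2  5  4 82 ]
G [  2  3  2  4  3 86 84  8 ]
T [ 93 92 91  7 90  6  6  6 ]
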