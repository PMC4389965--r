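>SYN_EVI1_LIKE synthetic EVI1-like matrix (invented stand-in, not an experimentally derived motif)
A [  2 14  1 13 15  1 14  2 13 ]
C [  1  2 15  2  1  2  1  1  2 ]
G [ 14  3  2  1  2 15  2  2  1 ]
T [  3  1  2  4  2  2  3 15  4 ]
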