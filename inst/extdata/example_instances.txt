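#universe_size=15
0 1 4 6 10 11 12 14
1 2 3 5 6 8 11
0 3 4 5 8 11 12 14
0 2 4 5 6 7 8 10 12 13
4 5 6 7 9 11 14
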