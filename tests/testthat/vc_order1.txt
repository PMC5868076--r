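# order-1 variance components, hand written
G 2
1.5
0.25 0.75
P 2
2.5
-0.5 1.25
SIGMA2E
0.8
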