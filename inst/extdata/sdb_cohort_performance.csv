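subject,accuracy_pct,kappa
1,76.07,0.58
2,75.30,0.48
3,65.11,0.39
4,78.49,0.63
5,68.11,0.41
6,79.81,0.67
7,82.62,0.62
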