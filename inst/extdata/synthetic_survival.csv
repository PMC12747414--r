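# Synthetic mutational-survival curve (no experimental data).
# Generated by prismr::simulate_survival_curve, truth alpha=0.104 beta=0.019,
# 1000 clones per n, seed 42.
n,assayed,functional
0,1000,1000
1,1000,883
2,1000,731
3,1000,598
4,1000,489
5,1000,394
6,1000,276
7,1000,187
8,1000,124
9,1000,90
10,1000,49
11,1000,30
12,1000,16
13,1000,13
14,1000,9
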