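# Synthetic ddG records (no experimental data), kcal/mol, positive = destabilizing.
# Drawn by prismr::simulate_ddg_sample from bigaussian(w=0.25, mu1=-0.6, s1=0.5, mu2=1.4, s2=1.1), seeds 42/43.
# synthProtB has fewer than 30 records and exercises the record filter.
protein,ddg
synthProtA,2.327
synthProtA,-1.5763
synthProtA,0.1464
synthProtA,1.0115
synthProtA,1.4458
synthProtA,-0.9078
synthProtA,0.0489
synthProtA,-0.7458
synthProtA,-1.1156
synthProtA,2.1323
synthProtA,2.2603
synthProtA,0.1635
synthProtA,-1.0555
synthProtA,0.5436
synthProtA,-0.5018
synthProtA,1.9325
synthProtA,2.5388
synthProtA,0.4323
synthProtA,-0.8149
synthProtA,-0.6354
synthProtA,1.3934
synthProtA,2.8443
synthProtA,-0.4517
synthProtA,0.5006
synthProtA,2.7566
synthProtA,2.4076
synthProtA,-0.3802
synthProtA,1.9909
synthProtA,1.5421
synthProtA,0.5458
synthProtA,-1.2104
synthProtA,2.6532
synthProtA,2.9194
synthProtA,1.9715
synthProtA,1.9908
synthProtA,-1.5048
synthProtA,1.7509
synthProtA,2.062
synthProtA,1.1349
synthProtA,2.4965
synthProtA,-0.0813
synthProtA,2.442
synthProtA,0.9678
synthProtA,-0.3058
synthProtA,0.9121
synthProtA,1.6773
synthProtA,0.4711
synthProtA,0.9552
synthProtA,3.4006
synthProtA,-0.494
synthProtA,0.6711
synthProtA,1.7004
synthProtA,1.9854
synthProtA,2.7933
synthProtA,-0.9811
synthProtA,1.8107
synthProtA,-0.0813
synthProtA,1.0463
synthProtA,-0.2069
synthProtA,-0.6018
synthProtB,1.0143
synthProtB,-0.8134
synthProtB,1.8545
synthProtB,1.3012
synthProtB,-0.022
synthProtB,0.1291
synthProtB,-0.5343
synthProtB,0.7529
synthProtB,2.7426
synthProtB,-0.9265
synthProtB,2.8838
synthProtB,1.6498
synthProtB,1.5057
synthProtB,0.5813
synthProtB,1.7019
synthProtB,2.8606
synthProtB,2.3612
synthProtB,0.6167
synthProtB,-1.9652
synthProtB,1.7795
synthProtB,1.4207
synthProtB,-1.0927
synthProtB,-0.9591
synthProtB,4.3016
synthProtB,-2.1425
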