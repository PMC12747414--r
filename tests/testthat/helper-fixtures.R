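# Published hyper-exponential parameter sets used across tests
fit_bla <- hyperexp_fit(0.104, 0.019)    # beta-lactamase, L = 263
fit_gfp <- hyperexp_fit(-0.047, 0.054)   # GFP, L = 238
fit_hisa <- hyperexp_fit(0.096, 0.039)   # HisA, L = 254

# asymmetric two-component mixture for ddG tests (kcal/mol)
mix_test <- bigaussian(w = 0.3, mu1 = -0.8, s1 = 0.6, mu2 = 1.6, s2 = 1.2)

# noiseless curve generated from a fit over a given n range
noiseless_curve <- function(fit, n) survival_curve(n, prop = eval_pn(fit, n))
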