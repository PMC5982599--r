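[{"descriptor":"VISNIR.414.R_minus_skin.min","upper":0.8,"lower":-0.33},{"descriptor":"VISNIR.477.A.std","upper":0.082,"lower":0.039},{"descriptor":"VISNIR.477.A.energy","upper":0.125,"lower":0.046},{"descriptor":"VISNIR.524.R.energy","upper":0.28,"lower":0.03},{"descriptor":"VISNIR.671.R.mu3","upper":0.0018,"lower":-2},{"descriptor":"VISNIR.995.R.mean","upper":0.55,"lower":0.4},{"descriptor":"EXNIR.1214.A_minus_skin.std","upper":0.082,"lower":0.04},{"descriptor":"EXNIR.1613.A.min","upper":1.95,"lower":1.18}]
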