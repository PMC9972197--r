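# model: synthetic
# s0: 0.80000000000000004
# scale: 1
covariate,beta,mean
age,0.094320796239162646,70
sbp,0.032656501748345383,140
male,0.3983100740585509,0.46500000000000002
diabetes,0.63840563907637893,0.19
smoking,0.54109375207162413,0.20000000000000001
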