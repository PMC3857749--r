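# SYNTHETIC parameter set (constructed by numerical search, not from any
# published table): genuine subcritical Hopf at gamma ~ 0.0539; at this
# gamma the larger equilibrium is a stable focus encircled by an unstable
# limit cycle of period ~1.19.
A: 2.88
d: 0.0108
beta: 2.82
m: 8.83
gamma: 0.058
alpha: 0.00102
p: 0.916
k: 6.59
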