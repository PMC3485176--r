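# Default kinetic parameters of the synthetic bacteria-yeast ecosystem.
# All values in the units documented in ?eco_params. An empty file (or any
# omitted key) falls back to these same defaults.
k1: 0.234
k2: 0.936
cmax: 1.0e9
k3: 4.0e6
Gc: 3.0e-7
alpha: 5.0e4
alpha_unit: molecules
k4: 5.0e-6
k5: 5.0e-6
k6: 3.0e19
k9: 3.0e19
AHLR1_conc: 5.0e-7
AHLR2_conc: 5.0e-7
k7: 6.0e-5
k10: 6.0e-5
k7b: 1.0e-8
k10b: 1.0e-8
n1: 1
n2: 1
k8: 5
k11: 1.19
k12: 1.19
k13: 1.386
k14: 1.386
k15: 4
k16: 4
V1: 3.7e-14
V2: 1.0e-15
Na: 6.023e23
d: 0
noise_scale: 1
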