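name: T2DMC
Ib: 60.3
Gb: 161.8
Vmax: 0.032
K: 150.2
beta: 12.1
kp3: 0.005
body_mass: 74
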