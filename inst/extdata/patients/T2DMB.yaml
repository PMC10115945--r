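name: T2DMB
Ib: 59.3
Gb: 146.1
Vmax: 0.039
K: 270.1
beta: 20.0
kp3: 0.006
body_mass: 74
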