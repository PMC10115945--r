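name: T2DMA
Ib: 57.9
Gb: 120.8
Vmax: 0.042
K: 397.0
beta: 27.3
kp3: 0.007
body_mass: 74
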