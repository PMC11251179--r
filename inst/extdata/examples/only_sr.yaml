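# Four-compartment chain, self-renewal only; terminal compartment inert.
N: 4
lambda: [0.9, 0.9, 0.9, 0.0]
s: [0.0, 0.0, 0.0, 0.0]
a: [0.0, 0.0, 0.0, 0.0]
nu: [0.5, 0.5, 0.5, 0.0]
xi: [0.0, 0.0, 0.0, 0.0]
mu: [1.0, 1.0, 1.0, 0.0]
label: four compartments, only SR
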