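# Reference scenario: 1500-patient waiting list, 500 grafts, exponential
# tumor sizes (lambda = 0.3 /cm), 5-year horizon, Milan cutoff 5 cm.
# delta1 = 0.3 is the calibrated-crossing convention (hazards cross near 7 cm).
alpha0: 0.048
alpha1: 2
delta1: 0.3
delta2: 0.006
lambda: 0.3
T: 5
N: 1500
F: 500
S_M: 5
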