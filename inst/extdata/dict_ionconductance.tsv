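T-type calcium conductance
T-type calcium conductances
T-type Ca2+ conductance
T-type Ca2+ conductances
L-type calcium conductance
persistent sodium conductance
transient sodium conductance
A-type potassium conductance
delayed rectifier potassium conductance
hyperpolarization-activated conductance
inward rectifier conductance
leak conductance
h-conductance
low-threshold calcium conductance
high-threshold calcium conductance
calcium-activated potassium conductance
gH
gT
gNa
gNaP
gKir
gKdr
gA
gK
gCa
gL
g(Ts)
gK(Ca)
gh
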