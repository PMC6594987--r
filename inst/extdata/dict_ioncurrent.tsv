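T-type calcium current
T-type calcium currents
T-type Ca2+ current
T-type Ca2+ currents
L-type calcium current
persistent sodium current
transient sodium current
A-type potassium current
delayed rectifier potassium current
hyperpolarization-activated current
inward rectifier current
leak current
h-current
low-threshold calcium current
high-threshold calcium current
calcium-activated potassium current
IH
IT
INa
INaP
IKir
IKdr
IA
IK
ICa
IL
I(Ts)
IK(Ca)
Ih
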