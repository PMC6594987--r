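T-type calcium channel
T-type calcium channels
T-type Ca2+ channel
T-type Ca2+ channels
L-type calcium channel
L-type calcium channels
sodium channel
sodium channels
potassium channel
potassium channels
calcium channel
calcium channels
HCN channel
HCN channels
HCN1
HCN2
HCN4
Cav3.1
Cav3.2
Cav3.3
CaV3.1
Nav1.1
Nav1.2
Nav1.6
Kv1.1
Kv3.1
Kv4.2
Kir2.1
SK channel
SK channels
BK channel
BK channels
CACNA1G
CACNA1H
CACNA1I
alpha1G
alpha1H
alpha1I
CaVT
KCNQ2
KCNQ3
SCN1A
SCN8A
NMDA receptor channel
AMPA receptor channel
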