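ventral posterior medial nucleus
ventral posteromedial nucleus
VPM
ventrobasal complex
nucleus
suprachiasmatic nucleus
thalamus
cortex
hippocampus
cerebellum
striatum
amygdala
hypothalamus
neocortex
ventral posterior lateral nucleus
lateral geniculate nucleus
medial geniculate nucleus
reticular nucleus
thalamic reticular nucleus
barrel cortex
somatosensory cortex
visual cortex
auditory cortex
motor cortex
prefrontal cortex
entorhinal cortex
dentate gyrus
substantia nigra
subthalamic nucleus
globus pallidus
inferior colliculus
superior colliculus
olfactory bulb
brainstem
spinal cord
layer 4
layer 5
dorsal lateral geniculate nucleus
centrolateral nucleus
anterior thalamic nucleus
paraventricular nucleus
arcuate nucleus
locus coeruleus
raphe nucleus
red nucleus
caudate nucleus
putamen
claustrum
zona incerta
medial septum
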