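pyramidal neurons
pyramidal neuron
pyramidal cells
pyramidal cell
Martinotti cells
Martinotti cell
thalamo-cortical relay cell
thalamo-cortical relay cells
thalamocortical neurons
thalamocortical neuron
relay cells
relay cell
relay neurons
TC cells
TC cell
interneurons
interneuron
basket cells
basket cell
chandelier cells
granule cells
granule cell
Purkinje cells
Purkinje cell
stellate cells
stellate cell
bipolar cells
mitral cells
motoneurons
motoneuron
fast-spiking interneurons
low-threshold spiking interneurons
spiny stellate cells
medium spiny neurons
dopaminergic neurons
cholinergic neurons
GABAergic interneurons
GABAergic neurons
glutamatergic neurons
serotonergic neurons
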