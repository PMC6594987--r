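the	DT
a	DT
an	DT
this	DT
these	DT
that	DT
those	DT
each	DT
all	DT
some	DT
no	DT
abstract	NN
whole	JJ
cell	NN
cells	NNS	cell
voltage	NN
current	NN
currents	NNS	current
conductance	NN
channel	NN
channels	NNS	channel
recording	NN
recordings	NNS	recording
neuron	NN
neurons	NNS	neuron
neurone	NN	neuron
neurones	NNS	neuron
nucleus	NN
nuclei	NNS	nucleus
cortex	NN
thalamus	NN
complex	NN
region	NN
regions	NNS	region
area	NN
areas	NNS	area
pole	NN
rate	NN
effect	NN
firing	NN
membrane	NN
potential	NN
amplitude	NN
resistance	NN
slice	NN
slices	NNS	slice
rat	NN
rats	NNS	rat
mouse	NN
mice	NNS	mouse
is	VBZ	be
are	VBP	be
was	VBD	be
were	VBD	be
be	VB
been	VBN	be
being	VBG	be
has	VBZ	have
have	VBP	have
had	VBD	have
made	VBN	make
make	VB
makes	VBZ	make
shows	VBZ	show
shown	VBN	show
showed	VBD	show
increased	VBD	increase
decreased	VBD	decrease
observed	VBN	observe
recorded	VBN	record
measured	VBN	measure
blocked	VBN	block
ranged	VBD	range
substituted	VBN	substitute
detected	VBN	detect
found	VBN	find
suggest	VBP
suggests	VBZ	suggest
can	MD
may	MD
could	MD
will	MD
would	MD
in	IN
of	IN
on	IN
at	IN
by	IN
from	IN
to	TO
with	IN
within	IN
during	IN
for	IN
into	IN
between	IN
after	IN
before	IN
under	IN
per	IN
and	CC
or	CC
but	CC
nor	CC
not	RB
also	RB
only	RB
mainly	RB
partially	RB
respectively	RB
significantly	RB
strongly	RB
very	RB
vivo	FW
vitro	FW
situ	FW
et	FW
al	FW
ventral	JJ
dorsal	JJ
medial	JJ
lateral	JJ
rostral	JJ
caudal	JJ
posterior	JJ
anterior	JJ
spontaneous	JJ
heterogeneous	JJ
depolarizing	JJ
hyperpolarizing	JJ
orbital	JJ
cingulate	JJ
somatosensory	JJ
cortical	JJ
thalamic	JJ
persistent	JJ
tonic	JJ
normal	JJ
adult	JJ
other	JJ
same	JJ
several	JJ
small	JJ
large	JJ
high	JJ
low	JJ
mean	JJ
it	PRP
we	PRP
they	PRP
its	PRP$
their	PRP$
our	PRP$
which	WDT
when	WRB
where	WRB
than	IN
as	IN
due	JJ
such	JJ
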