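metre	m	meter
gram	g
second	s
ampere	A
kelvin	K
mole	mol
candela	cd
litre	l	liter	L
hertz	Hz
newton	N
pascal	Pa
joule	J
watt	W
coulomb	C
volt	V	v
farad	F
ohm	Ω
siemens	S
weber	Wb
tesla	T
henry	H
becquerel	Bq
gray	Gy
molar	M
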