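subfamily	subgroup	h2	h5	le1	le2
PIP	PIP	F	H	T	R
TIP	TIP1	H	I	A	R
TIP	TIP2	H	I	G	R
TIP	TIP3	H	V	A	R
TIP	TIP4	H	T	A	M
TIP	TIP4	H	I	A	V
TIP	TIP4	H	I	A	M
NIP	NIP1	A	I	G	R
NIP	NIP1	S	I	A	R
NIP	NIP2	G	S	G	R
NIP	NIP3	W	V	A	R
NIP	NIP3	W	I	A	R
NIP	NIP3	W	S	A	R
XIP	XIP1	I	T	A	R
SIP	SIP1	ILV	.	GP	SN
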