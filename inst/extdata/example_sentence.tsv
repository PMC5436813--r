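onset	duration	word	pos	phonemes
0.00	0.18	Ze	VNW(pers,pron,nomin)	z @
0.18	0.36	staat	WW(pv,tgw,met-t)	s t a t
0.54	0.36	stil	ADJ(vrij,basis,zonder)	s t I l
0.90	0.18	en	VG(neven)	E n
1.08	0.36	kijkt	WW(pv,tgw,met-t)	k EI k t
1.44	0.18	een	LID(onbep,stan,agr)	@ n
1.62	0.36	poosje	N(soort,ev,dim,onz,stan)	p o S @
1.98	0.27	naar	VZ(init)	n a r
2.25	0.18	een	LID(onbep,stan,agr)	@ n
2.43	0.36	punt	N(soort,ev,basis,onz,stan)	p y n t
2.79	0.18	in	VZ(init)	I n
2.97	0.18	de	LID(bep,stan,rest)	d @
3.15	0.45	verte	N(soort,ev,basis,zijd,stan)	v E r t @
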