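spot	morph	s01	s03	s04	s05	s06	s10	s11	s12	s13	s14	s15	s17	s18	s19	s20
s01	W	0.06	0.95	0.96	0.99	1	0.96	0.98	0.96	1	1	1	1	1	1	1
s03	W	0.95	0.13	0.95	0.98	1	0.96	0.99	0.99	0.99	1	1	1	1	1	1
s04	W	0.96	0.95	0.15	0.98	1	0.95	0.99	0.99	0.99	1	1	1	1	1	1
s05	W	0.99	0.98	0.98	0.1	1	0.97	0.99	0.99	0.99	1	1	1	1	1	1
s06	W	1	1	1	1	0.17	1	1	1	1	1	1	0.4	0.41	0.41	0.43
s10	W	0.96	0.96	0.95	0.97	1	0.17	0.96	0.97	0.99	1	1	1	1	1	1
s11	Y	0.98	0.99	0.99	0.99	1	0.96	0.21	0.98	0.99	1	1	1	1	1	1
s12	Y	0.96	0.99	0.99	0.99	1	0.97	0.98	0.38	0.99	1	1	1	1	1	1
s13	Y	1	0.99	0.99	0.99	1	0.99	0.99	0.99	0.55	1	0.99	1	1	1	1
s14	Y	1	1	1	1	1	1	1	1	1	0.62	0.99	1	1	1	1
s15	Y	1	1	1	1	1	1	1	1	0.99	0.99	0.56	1	1	1	1
s17	R	1	1	1	1	0.4	1	1	1	1	1	1	0.14	0.41	0.42	0.42
s18	R	1	1	1	1	0.41	1	1	1	1	1	1	0.41	0.15	0.4	0.41
s19	R	1	1	1	1	0.41	1	1	1	1	1	1	0.42	0.4	0.14	0.42
s20	R	1	1	1	1	0.43	1	1	1	1	1	1	0.42	0.41	0.42	0.15
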