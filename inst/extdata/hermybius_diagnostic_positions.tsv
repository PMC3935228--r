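position	hermybius	sosybius
64	T	C
73	G	A
82	T	C
118	C	T
133	C	T
235	C	T
238	A	G
364	C	T
436	C	T
526	A	T
616	C	T
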