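rsid	minor	major
rs660118	C	G
rs679581	C	T
rs754532	T	A
rs735942	A	G
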