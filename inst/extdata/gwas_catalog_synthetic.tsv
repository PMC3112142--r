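rsid	chrom	pos	ref	alt	trait
rs6265	11	27679916	C	T	smoking behavior; body mass index
rs6010620	20	61780283	G	A	high-grade glioma
rs660118	11	65363435	G	C	breast cancer
rs1001	1	150000	A	G	synthetic trait 1
rs1002	2	250000	C	T	synthetic trait 2
rs1003	3	350000	G	A	synthetic trait 3
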