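# 21 tumor-associated antigen genes (glioblastoma humoral immune response).
# Eight names are real antigen genes; the remainder are SYNTHETIC placeholders
# (SYNAG*) completing the list to 21 entries for testing.
SART1
DST
KIF5B
GPI
ZNF594
APBB1
ZNF324
ING4
SYNAG01
SYNAG02
SYNAG03
SYNAG04
SYNAG05
SYNAG06
SYNAG07
SYNAG08
SYNAG09
SYNAG10
SYNAG11
SYNAG12
SYNAG13
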