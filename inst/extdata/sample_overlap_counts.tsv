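sample1	sample2	only_1	only_2	both	percent
patientA_leuko	patientA_tumor	1924	1517	829	19.4
patientB_leuko	patientB_tumor	729	1558	798	25.9
patientA_leuko	patientB_leuko	2086	860	667	18.5
patientA_tumor	patientB_tumor	1654	1664	692	17.3
patientA_leuko	patientB_tumor	2044	1647	709	16.1
patientB_leuko	patientA_tumor	920	1739	607	18.6
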