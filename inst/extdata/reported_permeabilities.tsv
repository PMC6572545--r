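system	range	solute	Pm
choline-benzoate	full	CH4	8.3e-5
choline-benzoate	full	CO2	2.25
choline-benzoate	full	H2S	13.21
choline-lactate	full	CH4	7.6e-5
choline-lactate	full	CO2	1.22
choline-lactate	full	H2S	8.27
choline-benzoate	interface	CH4	6.8e-2
choline-benzoate	interface	CO2	50.0
choline-benzoate	interface	H2S	53.0
choline-lactate	interface	CH4	1.7e-1
choline-lactate	interface	CO2	28.4
choline-lactate	interface	H2S	33.1
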