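# schema_version: 1
# Count-based phenotype labels.
# method decreased_count: key = number of reduced-function alleles
#   (function decreased or no) in the diplotype.
# method expresser: key = number of normal-function alleles in the diplotype.
gene	method	key	label
SLCO1B1	decreased_count	0	NF
SLCO1B1	decreased_count	1	DF
SLCO1B1	decreased_count	2	PF
CYP3A5	expresser	0	Non-expresser
CYP3A5	expresser	1	Expresser
CYP3A5	expresser	2	Expresser
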