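# schema_version: 1
# Function-pair phenotype lookup: label keyed by the diplotype's counts of
# no-function (n_no), decreased-function (n_dec) and increased-function
# (n_inc) alleles; remaining alleles are normal-function. Combinations not
# listed are not realisable with the panel's allele set.
gene	n_no	n_dec	n_inc	label
CYP2C19	0	0	0	NM
CYP2C19	0	0	1	RM
CYP2C19	0	0	2	UM
CYP2C19	1	0	0	IM
CYP2C19	1	0	1	IM
CYP2C19	2	0	0	PM
CYP2B6	0	0	0	NM
CYP2B6	0	1	0	IM
CYP2B6	0	2	0	PM
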