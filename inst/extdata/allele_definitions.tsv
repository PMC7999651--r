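# schema_version: 1
# Star-allele definitions: each named allele is defined by the variant allele
# at its defining rsid. function: normal/decreased/no/increased function of
# the resulting protein; activity: per-allele activity value for genes
# phenotyped via an activity score (NA otherwise). priority orders allele
# assignment when more variant alleles are present than the two haplotype
# slots (lower number = assigned first; loss-of-function before decreased
# function). Reference alleles (*1, or CYP1A2 *1A) carry no defining variant
# and are listed with rsid NA; they fill unassigned haplotype slots.
# CYP2D6 *8 and *14 share rs5030865 with different alternate bases.
# UGT2B7 rs7439366: star labels for this variant are used inconsistently in
# the literature; the nucleotide genotype is the ground truth here and the
# star label is an alias only.
# CYP2B6 *4 (rs2279343) is genotyped but does not participate in phenotype
# assignment (only *5 and *9 do); it is annotation-only in the panel.
gene	allele	rsid	variant_allele	function	activity	priority
SLCO1B1	*1	NA	NA	normal	NA	99
SLCO1B1	*1B	rs2306283	G	normal	NA	2
SLCO1B1	*5	rs4149056	C	decreased	NA	1
CYP3A5	*1	NA	NA	normal	NA	99
CYP3A5	*3	rs776746	G	no	NA	1
CYP3A5	*6	rs10264272	T	no	NA	2
CYP2D6	*1	NA	NA	normal	1	99
CYP2D6	*3	rs35742686	del	no	0	1
CYP2D6	*4	rs3892097	A	no	0	2
CYP2D6	*6	rs5030655	del	no	0	3
CYP2D6	*7	rs5030867	C	no	0	4
CYP2D6	*8	rs5030865	T	no	0	5
CYP2D6	*14	rs5030865	A	no	0	6
CYP2D6	*9	rs5030656	del	decreased	0.5	7
CYP2D6	*10	rs1065852	A	decreased	0.25	8
CYP2D6	*17	rs28371706	T	decreased	0.5	9
CYP2D6	*41	rs28371725	A	decreased	0.5	10
CYP2C9	*1	NA	NA	normal	1	99
CYP2C9	*2	rs1799853	T	decreased	0.5	2
CYP2C9	*3	rs1057910	C	no	0	1
CYP2C19	*1	NA	NA	normal	NA	99
CYP2C19	*2	rs4244285	A	no	NA	1
CYP2C19	*3	rs4986893	A	no	NA	2
CYP2C19	*4	rs28399504	G	no	NA	3
CYP2C19	*17	rs12248560	T	increased	NA	4
CYP2B6	*1	NA	NA	normal	NA	99
CYP2B6	*9	rs3745274	T	decreased	NA	1
CYP2B6	*5	rs3211371	T	normal	NA	2
CYP1A2	*1A	NA	NA	normal	1	99
CYP1A2	*1C	rs2069514	A	decreased	0.5	1
CYP1A2	*1F	rs762551	A	increased	1.5	2
CYP1A2	*1B	rs2470890	T	normal	1	3
CYP2C8	*1	NA	NA	normal	NA	99
CYP2C8	*2	rs11572103	A	decreased	NA	2
CYP2C8	*3	rs10509681	C	decreased	NA	1
CYP2C8	*4	rs1058930	G	decreased	NA	3
CYP2A6	*1	NA	NA	normal	NA	99
CYP2A6	*9	rs28399433	G	decreased	NA	1
CYP3A4	*1	NA	NA	normal	NA	99
CYP3A4	*20	rs67666821	del	no	NA	1
CYP3A4	*6	rs4646438	del	no	NA	2
CYP3A4	*2	rs55785340	G	decreased	NA	3
CYP3A4	*22	rs35599367	T	decreased	NA	4
SLC22A1	*1	NA	NA	normal	NA	99
SLC22A1	*2	rs72552763	del	decreased	NA	1
SLC22A1	*3	rs12208357	T	decreased	NA	2
SLC22A1	*5	rs34059508	A	decreased	NA	3
UGT1A1	*1	NA	NA	normal	NA	99
UGT1A1	*28	rs887829	T	decreased	NA	1
UGT2B7	*1	NA	NA	normal	NA	99
UGT2B7	*2	rs7439366	C	decreased	NA	1
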