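# schema_version: 1
# Genotyping panel: the candidate-gene variant set (60 variants, 15 genes)
# used by the translation layer. "ref"/"alt" are the allele tokens the
# package matches against calls; "del" denotes a deletion allele and the
# alt token of a star-defining variant is the star-allele-defining base.
# star_allele: star label unequivocally defined by the alt allele (NA when
# the variant does not define an allele on its own).
# annotation_only: genotyped and carried through but not used in phenotype
# assignment. core_haplotype: member of the reduced ABCB1 haplotype
# (C3435T, G2677T/A, C1236T), the subset with the strongest reported effect
# on transporter activity/expression.
# Note: rs2032582 is triallelic (T or A alternate); the A allele is accepted
# as a variant token as well. rs5030865 carries two alternate bases (T, A)
# defining two distinct CYP2D6 alleles; both rows appear in the allele
# definition table keyed by (rsid, variant allele).
gene	rsid	ref	alt	star_allele	annotation_only	core_haplotype
CYP1A2	rs2069514	G	A	*1C	FALSE	FALSE
CYP1A2	rs762551	C	A	*1F	FALSE	FALSE
CYP1A2	rs2470890	C	T	*1B	FALSE	FALSE
CYP2A6	rs28399433	T	G	*9	FALSE	FALSE
CYP2B6	rs3745274	G	T	*9	FALSE	FALSE
CYP2B6	rs3211371	C	T	*5	FALSE	FALSE
CYP2B6	rs2279343	A	G	*4	TRUE	FALSE
CYP2B6	rs2279345	T	C	NA	TRUE	FALSE
CYP2B6	rs4803419	C	T	NA	TRUE	FALSE
CYP2C8	rs11572103	T	A	*2	FALSE	FALSE
CYP2C8	rs10509681	T	C	*3	FALSE	FALSE
CYP2C8	rs1058930	C	G	*4	FALSE	FALSE
CYP2C9	rs1799853	C	T	*2	FALSE	FALSE
CYP2C9	rs1057910	A	C	*3	FALSE	FALSE
CYP2C19	rs4244285	G	A	*2	FALSE	FALSE
CYP2C19	rs4986893	G	A	*3	FALSE	FALSE
CYP2C19	rs28399504	A	G	*4	FALSE	FALSE
CYP2C19	rs12248560	C	T	*17	FALSE	FALSE
CYP2D6	rs35742686	A	del	*3	FALSE	FALSE
CYP2D6	rs3892097	G	A	*4	FALSE	FALSE
CYP2D6	rs5030655	T	del	*6	FALSE	FALSE
CYP2D6	rs5030867	A	C	*7	FALSE	FALSE
CYP2D6	rs5030865	G	T	*8	FALSE	FALSE
CYP2D6	rs5030656	CTT	del	*9	FALSE	FALSE
CYP2D6	rs1065852	G	A	*10	FALSE	FALSE
CYP2D6	rs28371706	C	T	*17	FALSE	FALSE
CYP2D6	rs28371725	G	A	*41	FALSE	FALSE
CYP3A4	rs35599367	C	T	*22	FALSE	FALSE
CYP3A4	rs55785340	A	G	*2	FALSE	FALSE
CYP3A4	rs4646438	A	del	*6	FALSE	FALSE
CYP3A4	rs67666821	G	del	*20	FALSE	FALSE
CYP3A5	rs776746	A	G	*3	FALSE	FALSE
CYP3A5	rs10264272	C	T	*6	FALSE	FALSE
CYP4F2	rs2108622	C	T	*3	TRUE	FALSE
ABCB1	rs1045642	C	T	NA	FALSE	TRUE
ABCB1	rs2032582	G	T	NA	FALSE	TRUE
ABCB1	rs1128503	C	T	NA	FALSE	TRUE
ABCB1	rs10276036	C	T	NA	FALSE	FALSE
ABCB1	rs7787082	G	A	NA	FALSE	FALSE
ABCB1	rs4728709	C	T	NA	FALSE	FALSE
ABCB1	rs10248420	T	C	NA	FALSE	FALSE
ABCB1	rs10280101	T	G	NA	FALSE	FALSE
ABCB1	rs12720067	G	A	NA	FALSE	FALSE
ABCB1	rs11983225	A	G	NA	FALSE	FALSE
ABCB1	rs4148737	A	G	NA	FALSE	FALSE
ABCB1	rs3842	T	C	NA	FALSE	FALSE
ABCC2	rs2273697	G	A	NA	TRUE	FALSE
ABCC2	rs717620	C	T	NA	TRUE	FALSE
SLCO1B1	rs2306283	A	G	*1B	FALSE	FALSE
SLCO1B1	rs4149056	T	C	*5	FALSE	FALSE
SLCO1B1	rs4149015	G	A	NA	TRUE	FALSE
SLCO1B1	rs11045879	T	C	NA	TRUE	FALSE
SLC22A1	rs72552763	GAT	del	*2	FALSE	FALSE
SLC22A1	rs12208357	C	T	*3	FALSE	FALSE
SLC22A1	rs34059508	G	A	*5	FALSE	FALSE
UGT1A1	rs887829	C	T	*28	TRUE	FALSE
UGT1A1	rs35350960	C	A	NA	TRUE	FALSE
UGT1A1	rs4124874	T	G	NA	TRUE	FALSE
UGT1A1	rs4148323	G	A	NA	TRUE	FALSE
UGT2B4	rs4557343	T	C	NA	TRUE	FALSE
UGT2B7	rs7439366	T	C	*2	TRUE	FALSE
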