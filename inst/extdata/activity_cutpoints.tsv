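# schema_version: 1
# Activity-score to phenotype cutpoints (inclusive bounds; scores fall on a
# 0.25 grid so the bins are exhaustive for realisable diplotypes).
# CYP2D6 labels: PM poor, IM intermediate, NM normal, UM ultrarapid
# metabolizer; score scales with gene copy number (whole-gene deletion on
# both chromosomes gives score 0).
# CYP1A2 convention: reference *1A activity 1, *1C 0.5 (reduced), *1F 1.5
# (hyperinducible), *1B 1; diplotype scores below 2 are labelled Decreased,
# exactly 2 Normal, above 2 Rapid (inducibility-based convention).
gene	min_score	max_score	label
CYP2D6	0	0	PM
CYP2D6	0.25	1	IM
CYP2D6	1.25	2.25	NM
CYP2D6	2.5	Inf	UM
CYP2C9	0	0.5	PM
CYP2C9	1	1.5	IM
CYP2C9	2	2	NM
CYP1A2	0	1.75	Decreased
CYP1A2	2	2	Normal
CYP1A2	2.25	Inf	Rapid
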