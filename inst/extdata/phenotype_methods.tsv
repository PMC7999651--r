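# schema_version: 1
# Per-gene phenotype assignment method.
#   decreased_count: label from the count of reduced-function alleles
#     (decreased or no function) in the diplotype (see phenotype_counts.tsv).
#   expresser: label from the count of functional (normal-function) alleles;
#     a carrier of at least one functional allele expresses the enzyme.
#   activity_score: sum of per-allele activity values (scaled by gene copy
#     number where uses_copy_number) mapped through activity_cutpoints.tsv.
#   cpic_function: label looked up from the per-diplotype counts of
#     no-function / decreased-function / increased-function alleles
#     (see phenotype_function_maps.tsv).
#   diplotype_only: diplotype reported, no phenotype label.
# reference_allele fills haplotype slots with no defining variant.
gene	method	reference_allele	uses_copy_number
SLCO1B1	decreased_count	*1	FALSE
CYP3A5	expresser	*1	FALSE
CYP2D6	activity_score	*1	TRUE
CYP2C9	activity_score	*1	FALSE
CYP1A2	activity_score	*1A	FALSE
CYP2C19	cpic_function	*1	FALSE
CYP2B6	cpic_function	*1	FALSE
CYP2C8	diplotype_only	*1	FALSE
CYP2A6	diplotype_only	*1	FALSE
CYP3A4	diplotype_only	*1	FALSE
SLC22A1	diplotype_only	*1	FALSE
UGT1A1	diplotype_only	*1	FALSE
UGT2B7	diplotype_only	*1	FALSE
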