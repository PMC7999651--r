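# schema_version: 1
# Adverse drug reaction (ADR) counts in the reference cohort: 21 of 156
# volunteers reported 27 ADRs after a single 80 mg atorvastatin dose.
# gi = gastrointestinal symptoms (flatulence, loose stools, diarrhea);
# headache; myalgia = myalgia or arthralgia. "group" is the trial arm or sex
# stratum the cases fell in; denominator_n is the size of that stratum.
adr_type	group	cases	denominator_n
gi	E	10	36
gi	D	2	37
gi	B	1	30
gi	Total	13	156
headache	Female	11	85
headache	Male	0	71
headache	Total	11	156
myalgia	Total	3	156
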