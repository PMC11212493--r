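# Sequence-variant rules: the modified residue replaces the original mass
# columns: rule_id  target_residue  mode  mass_Da  label
K2C	K	replace	103.00919	UNIMOD:1132
T2A	T	replace	71.03711	UNIMOD:659
V2G	V	replace	57.02146	UNIMOD:672
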