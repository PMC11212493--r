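# Variable PTM rules: additive mass shifts (UNIMOD standard monoisotopic values)
# columns: rule_id  target_residue  mode  mass_Da  label
Oxidation	M	shift	15.994915	UNIMOD:35
Deamidation	N	shift	0.984016	UNIMOD:7
Deamidation	Q	shift	0.984016	UNIMOD:7
Phospho	S	shift	79.966331	UNIMOD:21
Phospho	T	shift	79.966331	UNIMOD:21
Phospho	Y	shift	79.966331	UNIMOD:21
Carbamidomethyl	C	shift	57.021464	UNIMOD:4
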