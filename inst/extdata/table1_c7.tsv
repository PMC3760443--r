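# Observed [M+H]+ of ghrelin species purified from stomach extracts of
# barfin flounder fed n-heptanoic acid (C7)-enriched feed.
# note: adduct = satellite species (+17); label_conflict = published
# label inconsistent with the glycine-donor amidation rule (a 21-residue
# amide has no donor residue; the same mass is labeled
# 20-(C10:0)-amide elsewhere). Both are excluded from strict label
# reproduction.
sample_id	group_label	mz	expected_form	note
c7_01	h (35-37)	2144.02	19-(C8:0)
c7_02	h (35-37)	2188.05	19-(C10:1) + 17	adduct
c7_03	i (38-40)	2170.03	19-(C10:1)
c7_04	i (38-40)	2298.07	21-(C10:1)
c7_05	j (42-45)	2300.08	21-(C10:0)
c7_06	k (45-47)	2172.04	19-(C10:0)
c7_07	l (48-50)	2240.09	20-(C10:1)-amide
c7_08	m (55-56)	2242.09	21-(C10:0)-amide	label_conflict
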