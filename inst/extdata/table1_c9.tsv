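# Observed [M+H]+ of ghrelin species purified from stomach extracts of
# barfin flounder fed n-nonanoic acid (C9)-enriched feed.
# note: adduct = satellite species (+1), excluded from strict label
# reproduction.
sample_id	group_label	mz	expected_form	note
c9_01	s (30-31)	2159.02	19-(C9:0) + 1	adduct
c9_02	s (30-31)	2001.95	18-(C9:0)
c9_03	t (35-37)	2144.02	19-(C8:0)
c9_04	t (35-37)	2168.02	19-(C10:2)
c9_05	t (35-37)	2286.09	21-(C9:0)
c9_06	u (38-41)	2158.03	19-(C9:0)
c9_07	v (45-46)	2172.04	19-(C10:0)
c9_08	w (49-50)	2228.07	20-(C9:0)-amide
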