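# Observed [M+H]+ of ghrelin species purified from stomach extracts of
# barfin flounder fed n-octanoic acid (C8)-enriched feed.
# note: anomalous = mass ~1.8 Da from the published label's theoretical
# value while every sibling row deviates <= 0.21 Da (probable misprint);
# excluded from strict label reproduction, not corrected. The duplicate
# 2170.03 row is printed twice in the source and kept.
sample_id	group_label	mz	expected_form	note
c8_01	o (33-37)	2146.02	19-(C8:0)	anomalous
c8_02	o (33-37)	2272.06	21-(C8:0)
c8_03	p (39-41)	2157.98	19-(C9:0)
c8_04	p (39-41)	2170.03	19-(C10:1)
c8_05	p (39-41)	2170.03	19-(C10:1)
c8_06	q (43-46)	2242.09	20-(C10:0)-amide
c8_07	r (55-56)	2214.07	20-(C8:0)-amide
c8_08	r (55-56)	2172.03	19-(C10:0)
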