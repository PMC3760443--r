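# Observed [M+H]+ of ghrelin species purified from stomach extracts of
# barfin flounder fed normal feed, with published form labels.
# group_label = carboxymethyl ion-exchange HPLC fraction group (elution
# time, min). note: adduct = satellite species (+24), excluded from
# strict label reproduction. The source table prints 2170.04 and 2298.09
# twice within group d; each is transcribed once here.
sample_id	group_label	mz	expected_form	note
cont01	c (33-37)	2144.12	19-(C8:0)
cont02	c (33-37)	2272.17	21-(C8:0)
cont03	c (33-37)	2168.03	19-(C8:0) + 24	adduct
cont04	c (33-37)	2296.07	21-(C8:0) + 24	adduct
cont05	d (38-40)	2158.04	19-(C9:0)
cont06	d (38-40)	2170.04	19-(C10:1)
cont07	d (38-40)	2286.09	21-(C9:0)
cont08	d (38-40)	2298.09	21-(C10:1)
cont09	e (43-46)	2214.19	20-(C8:0)-amide
cont10	e (43-46)	2238.10	20-(C10:2)-amide
cont11	e (43-46)	2172.06	19-(C10:0)
cont12	f (49-50)	2228.09	20-(C9:0)-amide
cont13	f (49-50)	2240.09	20-(C10:1)-amide
cont14	f (49-50)	2240.10	20-(C10:1)-amide
cont15	g (55-56)	2242.12	20-(C10:0)-amide
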