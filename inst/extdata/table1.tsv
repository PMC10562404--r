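# Comparison of selected morphological characters between the 12 species of
# the Schistura cincticauda species group (character comparison table of the
# group's revision). Cell grammar: INT | INT-INT | /RANGE + RANGE/ |
# state-token | token/token (polymorphism) | ? (unknown).
taxon	branched_dorsal_rays	pectoral_rays	pelvic_rays	caudal_rays	lateral_line_pores	supraorbital_pores	infraorbital_pores	supratemporal_pores	preoperculomandibular_pores	lip_dots	caudal_bar	dorsal_dot	dorsal_stripes	anus_position	lateral_line_length	axillary_lobe	lip_dots_second_pair	throat_blotch
Schistura_aurantiaca	7	9	7	/9 + 8/	6-26	7	/4 + 9/	3	9	present	light_thin	present	absent	middistance	intermediate	absent	absent	absent
Schistura_balteata	7	10-11	7	/8 + 8/	24-50	6	/4 + 11/	3	9	present/absent	absent	absent	present	middistance	long	present	absent	absent
Schistura_cincticauda	6-7	9	6-7	/9 + 8/	15-25	5	/4 + 10/	3	9	present/absent	dark_thick	present	absent	closer_pelvic	intermediate	absent	absent	absent
Schistura_crocotula	7	9	7	/8 + 8/	10-18	6	/4 + 9/	3	9	present	dark_thick	present	absent	closer_anal	short	absent	present	absent
Schistura_hartli	7	9	7	/8 + 8/	23-24	6	/4 + 9/	3	8	present	dark_thick	present	absent	middistance	intermediate	absent	absent	present
Schistura_ataranensis	7	9	7	/8 + 8/	18-31	6	/4 + 9/	3	9	present	dark_thick	absent	present	closer_pelvic	intermediate	present	absent	absent
Schistura_myaekanbawensis	7	8	7	/8 + 7/	12-18	6	/4 + 8-9/	3	9	present	dark_thick	present	absent	closer_pelvic	short	absent	present	absent
Schistura_kuehnei	7	9	7	/9 + 8/	14-22	6	/4 + 9/	3	9	present	incomplete	present	absent	middistance	intermediate	absent	absent	absent
Schistura_robertsi	7	7-8	7	/6-7 + 6-8/	7-12	6	/4 + 8/	4	9	present	dark_thick	present	absent	closer_anal	short	absent	absent	absent
Schistura_paucifasciata	7	10-11	7	/9 + 8?/	?	6	/4 + 11/	3	9	?	dark_thick	?	absent	closer_anal	intermediate	present	?	?
Schistura_peninsulae	7	9-10	7	/8-9 + 7-8/	9-15	5	/4 + 10/	3	9	present	dark_thick	present	absent	closer_anal	short	absent	absent	absent
Schistura_tenebrosa	7-8	9-10	7	/9 + 7-8/	18-30	6-8	/4 + 8-11/	3	7-10	present	dark_thick	present	absent	middistance	intermediate	present	absent	absent
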