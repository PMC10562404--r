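# 8 paratypes of S. robertsi from Phuket (MCZ 49164): 4 specimens with 7+8
# branched caudal-fin rays and 4 with 8+8. Pectoral counts were not reported
# for this lot and are left unobserved.
specimen	caudal_rays
mcz_49164_1	7+8
mcz_49164_2	7+8
mcz_49164_3	7+8
mcz_49164_4	7+8
mcz_49164_5	8+8
mcz_49164_6	8+8
mcz_49164_7	8+8
mcz_49164_8	8+8
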