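# 20 formalin-fixed specimens from 4 Phuket lots (ZRC 43693, 45718, 49182,
# 60821). All 20 have 8 pectoral-fin rays; 8 specimens have 7+7 or 7+8
# branched caudal-fin rays and 12 have 8+8. The published account does not
# split the 8 between 7+7 and 7+8; this fixture uses an even 4/4 split,
# which leaves every printed tally unchanged.
specimen	pectoral_rays	caudal_rays
zrc_phuket_01	8	7+7
zrc_phuket_02	8	7+7
zrc_phuket_03	8	7+7
zrc_phuket_04	8	7+7
zrc_phuket_05	8	7+8
zrc_phuket_06	8	7+8
zrc_phuket_07	8	7+8
zrc_phuket_08	8	7+8
zrc_phuket_09	8	8+8
zrc_phuket_10	8	8+8
zrc_phuket_11	8	8+8
zrc_phuket_12	8	8+8
zrc_phuket_13	8	8+8
zrc_phuket_14	8	8+8
zrc_phuket_15	8	8+8
zrc_phuket_16	8	8+8
zrc_phuket_17	8	8+8
zrc_phuket_18	8	8+8
zrc_phuket_19	8	8+8
zrc_phuket_20	8	8+8
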