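{
  "comment": [
    "Morphocode scheme of the species-group revision: 12 integer-coded",
    "characters A-L mapped onto the comparison-table characters. The",
    "published figure prints the state legends but not machine-readable",
    "per-species code strings; codes are derived from the matrix via the",
    "mappings below (auditable with derive_morphocode). Character L (body",
    "bars) has no matrix source row; its per-taxon codes come from the",
    "species Diagnoses and are shipped as direct assignments. Matrix values",
    "not covered by a legend are resolved by the range-overlap rule and",
    "flagged with a warning."
  ],
  "characters": [
    {"code": "A", "source": "pectoral_rays",
     "legend": "number of pectoral-fin rays (0 = 9, 1 = 10-11, 2 = 8)",
     "states": [
       {"code": "0", "values": [9]},
       {"code": "1", "values": [10, 11]},
       {"code": "2", "values": [8]}
     ]},
    {"code": "B", "source": "caudal_rays",
     "legend": "branched caudal-fin rays (0 = 9+8, 1 = 8+8, 2 = 7+8, 3 = 8+7)",
     "states": [
       {"code": "0", "formula": [9, 8]},
       {"code": "1", "formula": [8, 8]},
       {"code": "2", "formula": [7, 8]},
       {"code": "3", "formula": [8, 7]}
     ]},
    {"code": "C", "source": "lateral_line_length",
     "legend": "length of lateral line (0 = long, 1 = intermediate, 2 = short)",
     "states": [
       {"code": "0", "states": ["long"]},
       {"code": "1", "states": ["intermediate"]},
       {"code": "2", "states": ["short"]}
     ]},
    {"code": "D", "source": "anus_position",
     "legend": "position of anus (0 = half distance pelvic to anal, 1 = closer to pelvic fin, 2 = closer to anal fin)",
     "states": [
       {"code": "0", "states": ["middistance"]},
       {"code": "1", "states": ["closer_pelvic"]},
       {"code": "2", "states": ["closer_anal"]}
     ]},
    {"code": "E", "source": "lip_dots",
     "legend": "black dots on lower lip (0 = present, 1 = variable)",
     "states": [
       {"code": "0", "states": ["present"]},
       {"code": "1", "states": ["absent", "present"]}
     ]},
    {"code": "F", "source": "axillary_lobe",
     "legend": "axillary pelvic lobe (0 = absent, 1 = present)",
     "states": [
       {"code": "0", "states": ["absent"]},
       {"code": "1", "states": ["present"]}
     ]},
    {"code": "G", "source": "caudal_bar",
     "legend": "black bar on base of caudal fin (0 = present, 1 = absent, 2 = irregular)",
     "note": "the light, thin bar of S. aurantiaca is coded as state 0 (bar present); the figure caption does not separate it",
     "states": [
       {"code": "0", "states": ["dark_thick"]},
       {"code": "0", "states": ["light_thin"]},
       {"code": "1", "states": ["absent"]},
       {"code": "2", "states": ["incomplete"]}
     ]},
    {"code": "H", "source": "throat_blotch",
     "legend": "black blotch posterior of median incision of lower lip (0 = absent, 1 = present)",
     "states": [
       {"code": "0", "states": ["absent"]},
       {"code": "1", "states": ["present"]}
     ]},
    {"code": "I", "source": "lip_dots_second_pair",
     "legend": "second pair of black dots on lower lip (0 = absent, 1 = present)",
     "states": [
       {"code": "0", "states": ["absent"]},
       {"code": "1", "states": ["present"]}
     ]},
    {"code": "J", "source": "dorsal_dot",
     "legend": "black dot on base of dorsal fin (0 = present, 1 = absent)",
     "states": [
       {"code": "0", "states": ["present"]},
       {"code": "1", "states": ["absent"]}
     ]},
    {"code": "K", "source": "dorsal_stripes",
     "legend": "black bars on dorsal fin (0 = absent, 1 = present)",
     "states": [
       {"code": "0", "states": ["absent"]},
       {"code": "1", "states": ["present"]}
     ]},
    {"code": "L", "source": null,
     "legend": "bars of body (0 = bars numerous, broad or grey, 1 = 2 to 4 very thin black contrasting bars in middle of flank, 2 = all bars fused into plain brown body, 3 = most bars fused leaving few interspaces in middle of flank)",
     "direct": {
       "Schistura_balteata": "1",
       "Schistura_paucifasciata": "1",
       "Schistura_tenebrosa": "2",
       "Schistura_ataranensis": "3"
     },
     "default": "0"}
  ]
}
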