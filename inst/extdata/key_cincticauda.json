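{
  "comment": [
    "Encoding of the printed identification key to the species of the",
    "Schistura cincticauda species group (11 couplets, 12 terminal taxa).",
    "Each lead is a conjunction of predicates. Statements about live",
    "coloration, body colour pattern or geography have no character in the",
    "comparison-table matrix and are encoded as soft predicates: recorded,",
    "but excluded from routing unless explicitly enabled."
  ],
  "start": 1,
  "couplets": [
    {"id": 1, "leads": [
      {"predicates": [
        {"char": "axillary_lobe", "in": ["present"],
         "note": "axillary pelvic lobe present"}],
       "target": {"couplet": 2}},
      {"predicates": [
        {"char": "axillary_lobe", "in": ["absent"],
         "note": "no axillary pelvic lobe"}],
       "target": {"couplet": 5}}
    ]},
    {"id": 2, "leads": [
      {"predicates": [
        {"char": "body_bars", "soft": true,
         "note": "colour pattern of 2-4 thin dark bars below the dorsal fin"}],
       "target": {"couplet": 3}},
      {"predicates": [
        {"char": "body_bars", "soft": true,
         "note": "other colour pattern"}],
       "target": {"couplet": 4}}
    ]},
    {"id": 3, "leads": [
      {"predicates": [
        {"char": "caudal_bar", "in": ["absent"],
         "note": "no black bar at caudal-fin base"},
        {"char": "dorsal_saddles", "soft": true,
         "note": "3-5 black saddles on back"},
        {"char": "caudal_rays", "formula": {"upper": [8, 8], "lower": [8, 8]},
         "note": "8 + 8 branched caudal-fin rays"}],
       "target": {"taxon": "Schistura_balteata"}},
      {"predicates": [
        {"char": "caudal_bar", "in": ["dark_thick", "light_thin", "incomplete"],
         "note": "a black bar at caudal-fin base"},
        {"char": "dorsal_saddles", "soft": true, "note": "no dorsal saddles"},
        {"char": "caudal_rays", "formula": {"upper": [9, 9], "lower": [8, 8]},
         "note": "9 + 8 branched caudal-fin rays"}],
       "target": {"taxon": "Schistura_paucifasciata"}}
    ]},
    {"id": 4, "leads": [
      {"predicates": [
        {"char": "dorsal_stripes", "in": ["present"],
         "note": "dorsal fin with 2-3 black stripes"},
        {"char": "caudal_rays", "formula": {"upper": [8, 8], "lower": [8, 8]},
         "note": "8 + 8 branched caudal-fin rays"},
        {"char": "dorsal_dot", "in": ["absent"],
         "note": "no black mark on anterior dorsal-fin base"}],
       "target": {"taxon": "Schistura_ataranensis"}},
      {"predicates": [
        {"char": "dorsal_stripes", "in": ["absent"],
         "note": "dorsal fin with a single row of spots or plain"},
        {"char": "caudal_rays", "formula": {"upper": [9, 9], "lower": [8, 8]},
         "note": "9 + 8 branched caudal-fin rays"},
        {"char": "dorsal_dot", "in": ["present"],
         "note": "a prominent black mark on anterior dorsal-fin base"}],
       "target": {"taxon": "Schistura_tenebrosa"}}
    ]},
    {"id": 5, "leads": [
      {"predicates": [
        {"char": "anus_position", "in": ["closer_pelvic"],
         "note": "anus closer to pelvic-fin base than to anal-fin origin"}],
       "target": {"couplet": 6}},
      {"predicates": [
        {"char": "anus_position", "in": ["closer_anal", "middistance"],
         "note": "anus closer to anal-fin origin, or at equal distance"}],
       "target": {"couplet": 7}}
    ]},
    {"id": 6, "leads": [
      {"predicates": [
        {"char": "pectoral_rays", "count": [8, 8],
         "note": "8 pectoral-fin rays"},
        {"char": "caudal_rays", "formula": {"upper": [8, 8], "lower": [7, 7]},
         "note": "8 + 7 branched caudal-fin rays"},
        {"char": "lip_dots_second_pair", "in": ["present"],
         "note": "a second pair of black dots on lower lip near corners of mouth"}],
       "target": {"taxon": "Schistura_myaekanbawensis"}},
      {"predicates": [
        {"char": "pectoral_rays", "count": [9, 11],
         "note": "9-11 pectoral-fin rays"},
        {"char": "caudal_rays", "formula": {"upper": [9, 9], "lower": [8, 8]},
         "note": "9 + 8 branched caudal-fin rays"},
        {"char": "lip_dots_second_pair", "in": ["absent"],
         "note": "a single pair of black dots on lower lip"}],
       "target": {"taxon": "Schistura_cincticauda"}}
    ]},
    {"id": 7, "leads": [
      {"predicates": [
        {"char": "anus_position", "in": ["middistance"],
         "note": "anus at equal distance between pelvic-fin base and anal-fin origin"}],
       "target": {"couplet": 8}},
      {"predicates": [
        {"char": "anus_position", "in": ["closer_anal"],
         "note": "anus closer to anal-fin origin"}],
       "target": {"couplet": 9}}
    ]},
    {"id": 8, "leads": [
      {"predicates": [
        {"char": "caudal_rays", "formula": {"upper": [8, 8], "lower": [8, 8]},
         "note": "8 + 8 branched caudal-fin rays"},
        {"char": "caudal_bar", "in": ["dark_thick"],
         "note": "black bar at caudal-fin base regular, without interruption"},
        {"char": "throat_blotch", "in": ["present"],
         "note": "a black patch on throat behind the median interruption of lower lip"}],
       "target": {"taxon": "Schistura_hartli"}},
      {"predicates": [
        {"char": "caudal_rays", "formula": {"upper": [9, 9], "lower": [8, 8]},
         "note": "9 + 8 branched caudal-fin rays"},
        {"char": "caudal_bar", "in": ["incomplete"],
         "note": "black bar at caudal-fin base irregular, with interruption"},
        {"char": "throat_blotch", "in": ["absent"],
         "note": "no black patch on throat"}],
       "target": {"taxon": "Schistura_kuehnei"}}
    ]},
    {"id": 9, "leads": [
      {"predicates": [
        {"char": "caudal_rays", "lobe": "upper", "count": [6, 7],
         "note": "6-7 branched rays in upper caudal-fin lobe"},
        {"char": "pectoral_rays", "count": [7, 8],
         "note": "7-8 pectoral-fin rays"}],
       "target": {"taxon": "Schistura_robertsi"}},
      {"predicates": [
        {"char": "caudal_rays", "lobe": "upper", "count": [8, 9],
         "note": "8-9 branched rays in upper caudal-fin lobe"},
        {"char": "pectoral_rays", "count": [9, 11],
         "note": "9-11 pectoral-fin rays"}],
       "target": {"couplet": 10}}
    ]},
    {"id": 10, "leads": [
      {"predicates": [
        {"char": "interspace_colour", "soft": true,
         "note": "bars with yellowish interspaces in life, all very narrow and of similar width"}],
       "target": {"taxon": "Schistura_peninsulae"}},
      {"predicates": [
        {"char": "interspace_colour", "soft": true,
         "note": "bars with orange to red interspaces in life, wider than half the bar width"}],
       "target": {"couplet": 11}}
    ]},
    {"id": 11, "leads": [
      {"predicates": [
        {"char": "caudal_rays", "formula": {"upper": [8, 8], "lower": [8, 8]},
         "note": "8 + 8 branched caudal-fin rays"},
        {"char": "lateral_line_length", "in": ["short"],
         "note": "lateral line reaching at most halfway from pectoral-fin base to dorsal-fin origin"},
        {"char": "locality", "soft": true,
         "note": "coastal streams of the Gulf of Thailand slope"}],
       "target": {"taxon": "Schistura_crocotula"}},
      {"predicates": [
        {"char": "caudal_rays", "formula": {"upper": [9, 9], "lower": [8, 8]},
         "note": "9 + 8 branched caudal-fin rays"},
        {"char": "lateral_line_length", "in": ["intermediate"],
         "note": "lateral line reaching the vertical through the dorsal-fin origin"},
        {"char": "locality", "soft": true,
         "note": "headwaters of the Mae Klong, Ataran and Moei rivers"}],
       "target": {"taxon": "Schistura_aurantiaca"}}
    ]}
  ]
}
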