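{
  "comment": [
    "Per-taxon metadata for the comparison-table fixture. literature_derived",
    "marks the two species whose data come from earlier descriptions rather",
    "than from specimens examined for the revision. Notes record the cells",
    "where the typeset table and the Diagnosis prose disagree and how the",
    "fixture resolves them."
  ],
  "taxa": [
    {"taxon": "Schistura_aurantiaca", "has_molecular_data": true,
     "newly_described": false, "literature_derived": false,
     "notes": "caudal-fin bar printed 'Light, thin'; coded light_thin and mapped to the bar-present morphocode state with a note"},
    {"taxon": "Schistura_balteata", "has_molecular_data": true,
     "newly_described": false, "literature_derived": false, "notes": ""},
    {"taxon": "Schistura_cincticauda", "has_molecular_data": true,
     "newly_described": false, "literature_derived": false, "notes": ""},
    {"taxon": "Schistura_crocotula", "has_molecular_data": true,
     "newly_described": false, "literature_derived": false, "notes": ""},
    {"taxon": "Schistura_hartli", "has_molecular_data": true,
     "newly_described": true, "literature_derived": false, "notes": ""},
    {"taxon": "Schistura_ataranensis", "has_molecular_data": true,
     "newly_described": true, "literature_derived": false, "notes": ""},
    {"taxon": "Schistura_myaekanbawensis", "has_molecular_data": true,
     "newly_described": true, "literature_derived": false, "notes": ""},
    {"taxon": "Schistura_kuehnei", "has_molecular_data": true,
     "newly_described": true, "literature_derived": false, "notes": ""},
    {"taxon": "Schistura_robertsi", "has_molecular_data": true,
     "newly_described": false, "literature_derived": false, "notes": ""},
    {"taxon": "Schistura_paucifasciata", "has_molecular_data": false,
     "newly_described": false, "literature_derived": true,
     "notes": "pectoral rays 10-11 from the Diagnosis (table row ambiguous); unknown lip-mark cells kept as '?' (their apparent absence in the single old specimen may be a fixation artefact); caudal formula carries the printed uncertainty mark"},
    {"taxon": "Schistura_peninsulae", "has_molecular_data": true,
     "newly_described": true, "literature_derived": false,
     "notes": "pectoral rays 9-10 from the Diagnosis (typeset table row is a concatenation artefact)"},
    {"taxon": "Schistura_tenebrosa", "has_molecular_data": true,
     "newly_described": false, "literature_derived": true,
     "notes": "pectoral rays 9-10 from the Diagnosis (typeset table row is a concatenation artefact)"}
  ]
}
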