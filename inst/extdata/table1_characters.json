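{
  "comment": [
    "Character definitions for the comparison table of the Schistura",
    "cincticauda species-group revision (18 diagnostic characters; the",
    "table's sample size, standard length and invariant anal-fin ray rows",
    "are not characters). Qualitative vocabularies are closed and the",
    "printed free-text phrases are normalised to the tokens below",
    "(synonym map in 'synonyms'). Branched-ray counts drop the constant",
    "half-ray notation of the printed table. Pore counts are graded soft:",
    "the revision itself treats them as non-diagnostic between species.",
    "Infraorbital pores are printed as a two-part formula (4 + n) and use",
    "the same two-lobe formula kind as the caudal-ray formula."
  ],
  "characters": [
    {"id": "branched_dorsal_rays", "label": "Branched dorsal-fin rays",
     "kind": "count", "grade": "hard",
     "description": "Branched dorsal-fin rays; the last ray, split to its base, is counted as one."},
    {"id": "pectoral_rays", "label": "Pectoral-fin rays",
     "kind": "count", "grade": "hard",
     "description": "Number of pectoral-fin rays. The printed table row is a typesetting concatenation; values for S. paucifasciata, S. peninsulae and S. tenebrosa follow the species Diagnoses (10-11, 9-10 and 9-10 respectively)."},
    {"id": "pelvic_rays", "label": "Pelvic-fin rays", "kind": "count",
     "grade": "hard", "description": "Number of pelvic-fin rays."},
    {"id": "caudal_rays", "label": "Branched caudal-fin rays",
     "kind": "caudal_formula", "grade": "hard",
     "description": "Branched caudal-fin rays, upper lobe + lower lobe. The S. paucifasciata entry carries a printed uncertainty mark."},
    {"id": "lateral_line_pores", "label": "Lateral-line pores",
     "kind": "count", "grade": "soft",
     "description": "Number of lateral-line pores."},
    {"id": "supraorbital_pores", "label": "Supraorbital pores",
     "kind": "count", "grade": "soft",
     "description": "Number of supraorbital cephalic pores."},
    {"id": "infraorbital_pores", "label": "Infraorbital pores",
     "kind": "caudal_formula", "grade": "soft",
     "description": "Infraorbital cephalic pores, anterior + posterior part."},
    {"id": "supratemporal_pores", "label": "Supratemporal pores",
     "kind": "count", "grade": "soft",
     "description": "Number of supratemporal cephalic pores."},
    {"id": "preoperculomandibular_pores", "label": "Preoperculo-mandibular pores",
     "kind": "count", "grade": "soft",
     "description": "Number of preoperculo-mandibular cephalic pores."},
    {"id": "lip_dots", "label": "Black dots on lower lip",
     "kind": "qualitative", "vocabulary": ["present", "absent"],
     "grade": "hard",
     "description": "Pair of black marks on the lower lip, one on each side of the median interruption. 'Variable' entries are the polymorphism present/absent."},
    {"id": "caudal_bar", "label": "Black bar on caudal-fin base",
     "kind": "qualitative",
     "vocabulary": ["dark_thick", "light_thin", "incomplete", "absent"],
     "grade": "hard",
     "description": "Bar at the caudal-fin base: dark and thick, light and thin, incomplete (interrupted in the upper third), or absent."},
    {"id": "dorsal_dot", "label": "Black dot on dorsal-fin base",
     "kind": "qualitative", "vocabulary": ["present", "absent"],
     "grade": "hard",
     "description": "Prominent black mark on the base of the unbranched and first branched dorsal-fin rays."},
    {"id": "dorsal_stripes", "label": "Black stripes on dorsal fin",
     "kind": "qualitative", "vocabulary": ["present", "absent"],
     "grade": "hard",
     "description": "2-3 black stripes across the dorsal fin."},
    {"id": "anus_position", "label": "Position of anus",
     "kind": "qualitative",
     "vocabulary": ["closer_pelvic", "middistance", "closer_anal"],
     "grade": "hard",
     "description": "Anus closer to the pelvic-fin base, at mid-distance, or closer to the anal-fin origin."},
    {"id": "lateral_line_length", "label": "Length of lateral line",
     "kind": "qualitative", "vocabulary": ["short", "intermediate", "long"],
     "grade": "hard",
     "description": "short = ending before mid-distance from pectoral to pelvic-fin base; intermediate = ending around the dorsal-fin origin; long = ending behind the dorsal-fin base."},
    {"id": "axillary_lobe", "label": "Axillary pelvic lobe",
     "kind": "qualitative", "vocabulary": ["present", "absent"],
     "grade": "hard",
     "description": "Flap of tissue at the pelvic-fin base."},
    {"id": "lip_dots_second_pair", "label": "Second pair of black dots on lower lip",
     "kind": "qualitative", "vocabulary": ["present", "absent"],
     "grade": "hard",
     "description": "Additional pair of black marks on the lower lip near the corners of the mouth."},
    {"id": "throat_blotch", "label": "Black blotch on throat",
     "kind": "qualitative", "vocabulary": ["present", "absent"],
     "grade": "hard",
     "description": "Black patch on the throat posterior of the median incision of the lower lip."}
  ],
  "synonyms": {
    "Present": "present", "Absent": "absent",
    "Variable": "present/absent",
    "Dark, thick": "dark_thick", "Light, thin": "light_thin",
    "Incomplete": "incomplete",
    "Middistance pelvic-anal": "middistance",
    "Closer to pelvic fin": "closer_pelvic",
    "Closer to anal fin": "closer_anal",
    "Short": "short", "Intermediate": "intermediate", "Long": "long"
  }
}
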