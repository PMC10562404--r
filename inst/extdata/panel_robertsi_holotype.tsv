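# Holotype of S. robertsi, re-examined for the revision: 7+7 branched
# caudal-fin rays; 8 and 7 pectoral-fin rays (right and left), encoded as
# the observation set {7,8} (a set matches if any member matches).
specimen	pectoral_rays	caudal_rays
robertsi_holotype	{7,8}	7+7
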