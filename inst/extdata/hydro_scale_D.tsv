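# variant=D
# temperature=310.15
# viscosity=0.275
# radii=bondi
# probe_radius=0.15
# n_points=400
# conformation=alpha_helix
ALA	0.07544805397
ARG	0.06708164357
ASN	0.06404412873
ASP	0.07977381688
CYS	0.05825044141
GLN	0.058487229
GLU	0.06777604139
GLY	0.07601705497
HIS	0.05407661818
ILE	0.06646295424
LEU	0.06116338182
LYS	0.07154201534
MET	0.04742153957
PHE	0.04842358923
PRO	0.05892823295
SER	0.06212636793
THR	0.07153144949
TRP	0.04729186361
TYR	0.04870695879
VAL	0.06670445822
TERM_CAPPED	0.07153398521
TERM_ZWIT	0.07565791611
SESA_TERM	0.8654737787
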