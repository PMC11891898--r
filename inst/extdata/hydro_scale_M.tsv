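# variant=M
# temperature=310.15
# viscosity=0.275
# radii=bondi
# probe_radius=0.15
# n_points=400
# conformation=extended
ALA	0.08236497246
ARG	0.09322870178
ASN	0.09572933866
ASP	0.1143801002
CYS	0.08235639981
GLN	0.08553157961
GLU	0.1097660048
GLY	0.06413165405
HIS	0.09691941638
ILE	0.08517570838
LEU	0.09552813187
LYS	0.09892381178
MET	0.08394827204
PHE	0.0824375104
PRO	0.07381147596
SER	0.1029551007
THR	0.08910445933
TRP	0.0824047318
TYR	0.08913578585
VAL	0.08934875276
TERM_CAPPED	0.07153398521
TERM_ZWIT	0.106651956
SESA_TERM	0.8654737787
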