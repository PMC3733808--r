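# Compound codes (mainly metal ions) that are neither ligands themselves,
# nor rejection triggers, nor bridges for covalent grouping.
# One code per line; '#' starts a comment.  User-editable.
LI
NA
K
RB
CS
MG
CA
SR
BA
MN
FE
FE2
CO
NI
CU
CU1
ZN
CD
HG
AL
3CO
YB
PT
AU
AG
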