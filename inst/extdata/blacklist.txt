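# Compound codes never treated as ligands: solvents, buffers,
# cryoprotectants and other common crystallization additives.
# One code per line; '#' starts a comment.  User-editable.
# waters
HOH
DOD
WAT
# common anions / salts from crystallization conditions
SO4
PO4
NO3
ACT
FMT
CIT
CO3
OXL
TLA
TAR
MLI
AZI
SCN
CL
BR
IOD
F
NH4
# cryoprotectants and precipitants
GOL
EDO
PEG
PGE
PG4
1PE
P6G
MPD
MRD
DMS
EOH
MOH
IPA
ACY
ACN
BME
DTT
MES
EPE
TRS
BCT
CAC
IMD
PYR
BTB
FLC
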