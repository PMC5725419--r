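# Atom-name -> role mapping used by the trajectory readers.
# Edit or extend to match your force field's naming scheme and pass the
# file to role_map(path).
MG: LDH_METAL_MG
AL: LDH_METAL_AL
OH: LDH_HYDROXYL_O
HO: LDH_HYDROXYL_H
CT: C_TERM_C
C: C_TERM_C
OT1: C_TERM_O
OT2: C_TERM_O
"N": BACKBONE_N
OD1: SIDECHAIN_O
OD2: SIDECHAIN_O
CB: SIDECHAIN_OTHER
CG: SIDECHAIN_OTHER
OW: WATER_O
HW1: WATER_H
HW2: WATER_H
CL: COUNTERION
CLA: COUNTERION
"NA": COUNTERION
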