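# Atomic hydrophobicity constants f_i (logP-derived units), heavy atoms with
# implicit hydrogens.  Protein classes carry octanol/water fragment-style
# values; ALK_* is the united-alkane constant fixed by the methylene surface
# calibration (per-CH2 dot-surface MHP increment = 50 units at dot density
# 3/A^2, probe 1.4 A, decay length 2 A).
# table_version: 1
class	f
ALK_CH3	1.0218
ALK_CH2	1.0218
CH3_ALI	0.63
CH2_ALI	0.46
CH_ALI	0.24
C_ALI	0.05
C_ARO_H	0.34
C_ARO_SUB	0.11
C_CARBONYL	-0.29
C_CARBOXYL	-0.30
C_GUANIDINIUM	-0.30
N_AMIDE	-0.55
N_ARO	-0.50
N_CHARGED	-0.90
O_CARBONYL	-0.45
O_HYDROXYL	-0.40
O_CARBOXYLATE	-0.75
S_THIOL	0.40
S_THIOETHER	0.40
WALL_PHOBIC	1.0
WALL_PHILIC	-1.0
ELEM_C	0.20
ELEM_N	-0.50
ELEM_O	-0.50
ELEM_S	0.30
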