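# Three-group physicochemical partitions of the 20 amino acids used by the
# SVMProt-188D composition/transition/distribution descriptors.
# The polarizability medium group is CPNVEQIL: printed variants of this table
# sometimes duplicate G and omit C, which breaks the partition invariant
# (every residue in exactly one group) required for frequencies to sum to 1.
attribute	group_index	group_name	residues
hydrophobicity	1	polar	RKEDQN
hydrophobicity	2	neutral	GASTPHY
hydrophobicity	3	hydrophobic	CVLIMFW
vdw_volume	1	small	GASCTPD
vdw_volume	2	medium	NVEQIL
vdw_volume	3	large	MHKFRYW
polarity	1	low	LIFWCMVY
polarity	2	medium	PATGS
polarity	3	high	HQRKNED
polarizability	1	low	GASDT
polarizability	2	medium	CPNVEQIL
polarizability	3	high	KMHFRYW
charge	1	positive	KR
charge	2	neutral	ANCQGHILMFPSTWYV
charge	3	negative	DE
secondary_structure	1	helix	EALMQKRH
secondary_structure	2	strand	VIYCWFT
secondary_structure	3	coil	GNPSD
solvent_accessibility	1	buried	ALFCGIVW
solvent_accessibility	2	exposed	RKQEND
solvent_accessibility	3	intermediate	MPSTHY
surface_tension	1	large	GQDNAHR
surface_tension	2	medium	KTSEC
surface_tension	3	small	ILMFPWYV
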