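# Default physicochemical scales for the pseudo-amino-acid composition
# correlation factors. Columns (all user-replaceable via the same layout):
#   hydrophilic      Hopp-Woods hydrophilicity
#   hydrophobic      Kyte-Doolittle hydropathy
#   mass             monoisotopic residue mass (Da)
#   pK1              alpha-carboxyl pKa of the free amino acid
#   pK2              alpha-amino pKa of the free amino acid
#   pI               isoelectric point of the free amino acid
#   rigidity         negated Pickett-Sternberg side-chain conformational
#                    entropy (kcal/mol; higher = stiffer side chain)
#   flexibility      Bhaskaran-Ponnuswamy average flexibility index
#   irreplaceability BLOSUM62 self-substitution score (conservation proxy)
# Each scale is standardized to zero mean / unit variance over the 20
# residues before entering the correlation factors, so affine changes of
# any column leave the encoder output unchanged.
residue	hydrophilic	hydrophobic	mass	pK1	pK2	pI	rigidity	flexibility	irreplaceability
A	-0.5	1.8	71.03711	2.34	9.69	6.00	0.00	0.357	4
C	-1.0	2.5	103.00919	1.96	10.28	5.07	-1.14	0.346	9
D	3.0	-3.5	115.02694	1.88	9.60	2.77	-1.25	0.511	6
E	3.0	-3.5	129.04259	2.19	9.67	3.22	-1.81	0.497	5
F	-2.5	2.8	147.06841	1.83	9.13	5.48	-0.58	0.314	6
G	0.0	-0.4	57.02146	2.34	9.60	5.97	0.00	0.544	6
H	-0.5	-3.2	137.05891	1.82	9.17	7.59	-0.99	0.323	8
I	-1.8	4.5	113.08406	2.36	9.60	6.02	-0.89	0.462	4
K	3.0	-3.9	128.09496	2.18	8.95	9.74	-1.94	0.466	5
L	-1.8	3.8	113.08406	2.36	9.60	5.98	-0.78	0.365	4
M	-1.3	1.9	131.04049	2.28	9.21	5.74	-1.61	0.295	5
N	0.2	-3.5	114.04293	2.02	8.80	5.41	-1.57	0.463	6
P	0.0	-1.6	97.05276	1.99	10.60	6.30	0.00	0.509	7
Q	0.2	-3.5	128.05858	2.17	9.13	5.65	-2.02	0.493	5
R	3.0	-4.5	156.10111	2.17	9.04	10.76	-2.03	0.529	5
S	0.3	-0.8	87.03203	2.21	9.15	5.68	-1.71	0.507	4
T	-0.4	-0.7	101.04768	2.09	9.10	5.60	-1.63	0.444	5
V	-1.5	4.2	99.06841	2.32	9.62	5.96	-0.51	0.386	4
W	-3.4	-0.9	186.07931	2.83	9.39	5.89	-0.97	0.305	11
Y	-2.3	-1.3	163.06333	2.20	9.11	5.66	-0.98	0.420	7
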