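# 12-6 Lennard-Jones parameters for the methyl (-CH3) probe map.
# epsilon in kcal/mol, rmin is the per-atom minimum-distance contribution
# in Angstrom (Lorentz-Berthelot: rmin_ij = rmin_i + rmin_probe,
# eps_ij = sqrt(eps_i * eps_probe)). United-atom style values: protein
# heavy atoms are treated as extended atoms (implicit hydrogens).
# The CH3 row is the probe itself.
element	epsilon	rmin
C	0.150	2.00
N	0.160	1.85
O	0.200	1.70
S	0.250	2.00
P	0.200	2.10
SE	0.300	2.05
CH3	0.175	2.10
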