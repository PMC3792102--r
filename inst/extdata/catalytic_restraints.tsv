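# Flat-bottom NOE restraints maintaining the catalytic contact geometry of
# the glucuronidase active site (enzyme chain A, ligand chain B residue 1).
# Columns: chain_a res_a atom_a chain_b res_b atom_b d_min d_max k_min k_max
# Distances in angstrom; harmonic constants in kJ/(mol A^2).
A 413 HE2 B 1 O6 1.7 1.8 75.0 100.0
A 504 OE2 B 1 C1 2.5 2.6 75.0 100.0
A 467 HH12 B 1 O7 1.7 1.8 75.0 100.0
A 467 HH22 B 1 O8 1.7 1.8 75.0 100.0
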