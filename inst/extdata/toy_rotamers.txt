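ROT ALA 1 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
ROT ALA 1 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
ROT ARG 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT ARG 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT ASN 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT ASN 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT ASP 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT ASP 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT CYS 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT CYS 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT GLN 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT GLN 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT GLU 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT GLU 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT GLY 0 0.5
ROT GLY 0 0.5
ROT HIS 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT HIS 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT ILE 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT ILE 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT LEU 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT LEU 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT LYS 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT LYS 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT MET 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT MET 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT PHE 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT PHE 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT PRO 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT PRO 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT SER 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT SER 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT THR 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT THR 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT TRP 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT TRP 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT TYR 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT TYR 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
ROT VAL 2 0.59999999999999998
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -0.29727272727272724 -2.437272727272727 1.7681818181818181
ROT VAL 2 0.40000000000000002
CB -0.56999999999999995 -1.21 0.94999999999999996
CG -1.7972727272727269 -1.4827272727272727 1.7681818181818181
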