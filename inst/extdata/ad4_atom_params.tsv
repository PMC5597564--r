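# Per-atom-type parameters of the semi-empirical pairwise energy model.
# Rii: sum of vdW radii of two like atoms (A); epsii: vdW well depth
# (kcal/mol); vol: atomic solvation volume (A^3); solpar: atomic solvation
# parameter; hb: - (none), D (donor hydrogen), A (acceptor); hbRij/hbEps:
# 12-10 hydrogen-bond equilibrium distance (A) and well depth (kcal/mol)
# used when this acceptor pairs with a donor hydrogen.
type	Rii	epsii	vol	solpar	hb	hbRij	hbEps
H	2.00	0.020	0.0000	0.00051	-	0	0
HD	2.00	0.020	0.0000	0.00051	D	0	0
C	4.00	0.150	33.5103	-0.00143	-	0	0
A	4.00	0.150	33.5103	-0.00052	-	0	0
N	3.50	0.160	22.4493	-0.00162	-	0	0
NA	3.50	0.160	22.4493	-0.00162	A	1.90	5.0
OA	3.20	0.200	17.1573	-0.00251	A	1.90	5.0
F	3.09	0.080	15.4480	-0.00110	-	0	0
P	4.20	0.200	38.7924	-0.00110	-	0	0
S	4.00	0.200	33.5103	-0.00214	-	0	0
SA	4.00	0.200	33.5103	-0.00214	A	2.50	1.0
Cl	4.09	0.276	35.8235	-0.00110	-	0	0
Br	4.33	0.389	42.5661	-0.00110	-	0	0
I	4.72	0.550	55.0585	-0.00110	-	0	0
Ca	1.98	0.550	2.7700	-0.00110	-	0	0
Zn	1.48	0.550	1.7000	-0.00110	-	0	0
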