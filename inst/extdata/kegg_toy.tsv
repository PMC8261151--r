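#nodes
id	kind	label
C00132	metabolite	methanol
C00067	metabolite	formaldehyde
C00058	metabolite	formate
C00565	metabolite	trimethylamine
C00543	metabolite	dimethylamine
G_mdh	gene	mdh
G_fdh	gene	fdh
G_tmm	gene	tmm
G_dmd	gene	dmd
#edges
from	to	reaction	pathways
C00132	G_mdh	R1	P1
G_mdh	C00067	R2	P1
C00067	G_fdh	R3	P1
G_fdh	C00058	R4	P1
C00565	G_tmm	R5	P1,P2
G_tmm	C00543	R6	P2
C00543	G_dmd	R7	P2
G_dmd	C00067	R8	P2
#pathways
id	name
P1	Methane metabolism
P2	Methylamine degradation
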