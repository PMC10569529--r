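name	compartment	D_2d	D_3d	unit	group
Cdc42D_c	cytosol	15	15	um2 s-1	Cdc42
Cdc42D_m	membrane	0.0025	0.0025	um2 s-1	Cdc42
Cdc42T	membrane	0.0025	0.0025	um2 s-1	Cdc42
Bem1GEF_c	cytosol	15	15	um2 s-1	Bem1GEF
Bem1GEF_m	membrane	0.0025	0.0025	um2 s-1	Bem1GEF
Cdc42T_Bem1GEF	membrane	0.0025	0.0025	um2 s-1	Cdc42+Bem1GEF
Far1GEF_c	cytosol	15	15	um2 s-1	Far1GEF
RaGEF	membrane	0.0001	0.0001	um2 s-1	Far1GEF+Receptor
Ra_m	membrane	0.0001	0.0001	um2 s-1	Receptor
Ri_c	cytosol	15	15	um2 s-1	Receptor
Ri_m	membrane	0.0001	0.0001	um2 s-1	Receptor
Pheromone	extracellular	150	150	um2 s-1	none
Far1GEF_s	membrane	0	0	um2 s-1	Far1GEF
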