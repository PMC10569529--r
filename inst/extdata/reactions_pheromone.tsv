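label	reactants	products	order	rate_2d	unit_2d	rate_3d	unit_3d	rho	description
lambda_11	Ri_m+Pheromone	Ra_m	2	NA	s-1	1.8	s-1	0.05	Pheromone binding activates receptor
lambda_12	Ri_c+Cdc42T	Ri_m+Cdc42T	2	NA	s-1	0.625	s-1	0.05	Actin-implicit receptor delivery near Cdc42-GTP
k_13	Ra_m	Ri_m+Pheromone	1	NA	s-1	0.002	s-1	NA	Pheromone unbinding deactivates receptor
k_14	Ra_m	Ri_c+Pheromone	1	NA	s-1	0.002	s-1	NA	Internalization of active receptor releases pheromone
k_15	Ri_m	Ri_c	1	NA	s-1	0.0004	s-1	NA	Internalization of inactive receptor
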