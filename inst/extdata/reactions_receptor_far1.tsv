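label	reactants	products	order	rate_2d	unit_2d	rate_3d	unit_3d	rho	description
lambda_8a	Far1GEF_c+Ra_m	RaGEF	2	300	s-1	7500	s-1	0.05	Far1-GEF recruitment by active receptor
k_8b	RaGEF	Ra_m+Far1GEF_c	1	0.11	s-1	0.11	s-1	NA	Far1-GEF release from receptor
lambda_2c	Cdc42D_m+RaGEF	Cdc42T+RaGEF	2	180	s-1	180	s-1	0.05	Cdc42 activation by receptor-bound Far1-GEF
lambda_9	Ri_c+Cdc42T	Ra_m+Cdc42T	2	0.025	s-1	0.625	s-1	0.05	Actin-implicit receptor delivery near Cdc42-GTP
k_10	Ra_m	Ri_c	1	0.002	s-1	0.002	s-1	NA	Receptor internalization by endocytosis
k_10b	RaGEF	Far1GEF_c+Ri_c	1	0.002	s-1	0.002	s-1	NA	Internalization of receptor-Far1-GEF complex
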