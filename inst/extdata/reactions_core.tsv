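label	reactants	products	order	rate_2d	unit_2d	rate_3d	unit_3d	rho	description
k_1a	Bem1GEF_c	Bem1GEF_m	1	10	s-1	8.333	um s-1	NA	Bem1-GEF membrane association
k_1b	Bem1GEF_m	Bem1GEF_c	1	40	s-1	40	s-1	NA	Bem1-GEF membrane dissociation
lambda_2a	Bem1GEF_m+Cdc42D_m	Bem1GEF_m+Cdc42T	2	5.3	s-1	5.3	s-1	0.05	Cdc42 activation by membrane Bem1-GEF
k_2b	Cdc42T	Cdc42D_m	1	0.35	s-1	0.35	s-1	NA	Cdc42-GTP hydrolysis
lambda_3	Cdc42T_Bem1GEF+Cdc42D_m	Cdc42T_Bem1GEF+Cdc42T	2	180	s-1	180	s-1	0.05	Cdc42 activation by Cdc42T-bound Bem1-GEF
lambda_4a	Cdc42T+Bem1GEF_m	Cdc42T_Bem1GEF	2	9.6	s-1	40	s-1	0.05	Complex formation with membrane Bem1-GEF
k_4b	Cdc42T_Bem1GEF	Cdc42T+Bem1GEF_m	1	40	s-1	40	s-1	NA	Complex dissociation
k_5a	Cdc42D_c	Cdc42D_m	1	36	s-1	30	um s-1	NA	Cdc42-GDP membrane association
k_5b	Cdc42D_m	Cdc42D_c	1	13	s-1	13	s-1	NA	Cdc42-GDP membrane dissociation
lambda_7	Cdc42T+Bem1GEF_c	Cdc42T_Bem1GEF	2	256	s-1	6400	s-1	0.05	Complex formation with cytosolic Bem1-GEF
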