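label	reactants	products	order	rate_2d	unit_2d	rate_3d	unit_3d	rho	description
lambda_2c	Cdc42D_m+Far1GEF_s	Cdc42T+Far1GEF_s	2	180	s-1	180	s-1	0.05	Cdc42 activation by immobile membrane Far1-GEF seed
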