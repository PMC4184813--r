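metric	good	bad	weight
tm_score	1	0	1
noe_violation	0	2	1
ndope	-2	2	0.5
ddfire	-300	0	0.5
clash	0	100	1
rama_mol	100	0	0.5
rama_pro	100	0	0.5
pack1	0	-5	0.25
pack2	0	-5	0.25
rama_what	0	-5	0.5
rotamer	0	-5	0.25
backbone	0	-5	0.25
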