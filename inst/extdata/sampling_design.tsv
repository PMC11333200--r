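species	subgenus	A1	A2	N1	N2	G	total
S. capillifolium	Acutifolia	6	1	3	5	2	17
S. compactum	Rigida	3	0	3	5	2	13
S. divinum	Sphagnum	6	3	3	6	0	18
S. fimbriatum	Acutifolia	0	4	4	0	3	11
S. flexuosum	Cuspidata	0	3	3	6	2	14
S. fuscum	Acutifolia	6	3	3	5	2	19
S. lindbergii	Cuspidata	3	0	3	6	2	14
S. platyphyllum	Subsecunda	1	3	3	5	0	12
S. riparium	Cuspidata	3	2	3	5	1	14
S. squarrosum	Acutifolia	3	5	3	6	2	19
S. subnitens	Acutifolia	3	6	3	5	2	19
S. tenellum	Cuspidata	0	6	3	9	2	20
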