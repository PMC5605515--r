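opsin	bovine_pos	from	to	delta_nm	source
SWS1	46	F	T	8	violet/UV tuning site; synthetic-default
SWS1	49	F	L	3	violet/UV tuning site; synthetic-default
SWS1	52	T	F	6	violet/UV tuning site; synthetic-default
SWS1	86	F	Y	60	violet/UV switch; synthetic-default
SWS1	86	F	S	5	violet/UV tuning site; synthetic-default
SWS1	90	S	C	-46	violet/UV switch; synthetic-default
SWS1	93	T	P	10	violet/UV tuning site; synthetic-default
SWS1	114	A	G	4	violet/UV tuning site; synthetic-default
SWS1	116	L	V	-6	violet/UV tuning site; synthetic-default
SWS1	118	T	A	-3	violet/UV tuning site; synthetic-default
SWS1	265	W	Y	15	violet/UV tuning site; synthetic-default
SWS1	292	A	S	9	violet/UV tuning site; synthetic-default
SWS1	295	A	S	4	violet/UV tuning site; synthetic-default
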