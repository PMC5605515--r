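opsin	bovine_pos	from	to	delta_nm	source
LWS	164	A	S	6	measured: long-wavelength shift of the A164S replacement
LWS	164	S	A	-7	measured: short-wavelength shift of the S164A replacement
LWS	181	H	Y	-28	five-sites rule; synthetic-default
LWS	181	Y	H	28	five-sites rule; synthetic-default
LWS	261	Y	F	-8	five-sites rule; synthetic-default
LWS	261	F	Y	8	five-sites rule; synthetic-default
LWS	269	T	A	-16	five-sites rule; synthetic-default
LWS	269	A	T	16	five-sites rule; synthetic-default
LWS	292	A	S	-27	five-sites rule; synthetic-default
LWS	292	S	A	27	five-sites rule; synthetic-default
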