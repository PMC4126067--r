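motif_id	cell_types	location
ptm_1	CL_0000057,CL_0000091,CL_0000115,CL_0000182,CL_0000632	liver
ptm_2	CL_0000057,CL_0000115,CL_0000746,CL_0002068	heart
ptm_3	CL_0000057,CL_0000082,CL_0000115,CL_0000158,CL_0002598	lung
ptm_4	CL_0000057,CL_0000115,CL_0002071,CL_1000320	colon
ptm_5	CL_0000057,CL_0000115,CL_0000508,CL_0002182,CL_1000323	stomach
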