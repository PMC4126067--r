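term_id	CL_0000182	CL_0000632	CL_0000057	CL_0000091	CL_0000115	CL_0002068	CL_0000746	CL_0000158	CL_0000082	CL_0002598	CL_1000320	CL_0002071	CL_0002182	CL_0000508	CL_1000323
CL_0000182	1.000000	0.050000	0.050000	0.050000	0.050000	0.050000	0.290000	0.050000	0.460000	0.050000	0.050000	0.300000	0.050000	0.320000	0.050000
CL_0000632	0.050000	1.000000	0.050000	0.050000	0.050000	0.250000	0.050000	0.300000	0.050000	0.050000	0.240000	0.050000	0.290000	0.050000	0.050000
CL_0000057	0.050000	0.050000	1.000000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000
CL_0000091	0.050000	0.050000	0.050000	1.000000	0.050000	0.050000	0.050000	0.050000	0.050000	0.230000	0.050000	0.050000	0.050000	0.050000	0.170000
CL_0000115	0.050000	0.050000	0.050000	0.050000	1.000000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000	0.050000
CL_0002068	0.050000	0.250000	0.050000	0.050000	0.050000	1.000000	0.050000	0.050000	0.250000	0.050000	0.170000	0.050000	0.200000	0.050000	0.050000
CL_0000746	0.290000	0.050000	0.050000	0.050000	0.050000	0.050000	1.000000	0.050000	0.050000	0.640000	0.050000	0.220000	0.050000	0.230000	0.050000
CL_0000158	0.050000	0.300000	0.050000	0.050000	0.050000	0.050000	0.050000	1.000000	0.050000	0.050000	0.300000	0.050000	0.350000	0.050000	0.050000
CL_0000082	0.460000	0.050000	0.050000	0.050000	0.050000	0.250000	0.050000	0.050000	1.000000	0.050000	0.050000	0.290000	0.050000	0.310000	0.050000
CL_0002598	0.050000	0.050000	0.050000	0.230000	0.050000	0.050000	0.640000	0.050000	0.050000	1.000000	0.050000	0.050000	0.050000	0.050000	0.210000
CL_1000320	0.050000	0.240000	0.050000	0.050000	0.050000	0.170000	0.050000	0.300000	0.050000	0.050000	1.000000	0.050000	0.050000	0.050000	0.520000
CL_0002071	0.300000	0.050000	0.050000	0.050000	0.050000	0.050000	0.220000	0.050000	0.290000	0.050000	0.050000	1.000000	0.330000	0.050000	0.050000
CL_0002182	0.050000	0.290000	0.050000	0.050000	0.050000	0.200000	0.050000	0.350000	0.050000	0.050000	0.050000	0.330000	1.000000	0.050000	0.050000
CL_0000508	0.320000	0.050000	0.050000	0.050000	0.050000	0.050000	0.230000	0.050000	0.310000	0.050000	0.050000	0.050000	0.050000	1.000000	0.050000
CL_1000323	0.050000	0.050000	0.050000	0.170000	0.050000	0.050000	0.050000	0.050000	0.050000	0.210000	0.520000	0.050000	0.050000	0.050000	1.000000
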