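@HD	VN:1.6	GO:query
@SQ	SN:chr1	LN:500
@SQ	SN:chr2	LN:400
t01	99	chr1	11	60	50M	=	161	200	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	YD:Z:f
t01	147	chr1	161	60	50M	=	11	-200	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	YD:Z:f
t02	99	chr1	11	60	50M	=	161	200	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	YD:Z:f
t02	147	chr1	161	60	50M	=	11	-200	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	YD:Z:f
t03	99	chr1	11	60	50M	=	161	200	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	YD:Z:r
t03	147	chr1	161	60	50M	=	11	-200	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	YD:Z:r
t04	0	chr2	101	60	5S45M	*	0	0	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	XG:Z:CT
t05	77	*	0	0	*	*	0	0	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
t05	141	*	0	0	*	*	0	0	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
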