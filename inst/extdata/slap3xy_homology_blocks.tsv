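id	x_start	x_end	x_length	y_start	y_end	y_length	direction	evalue	identity_pct	k	se_k
1	3586	5587	2002	71985	70005	1981	Inverted	0	73	0.14	0.012
2	16253	17744	1492	8055	9530	1474	Direct	0	76	0.11	0.010
3	17735	18992	1258	3248	1996	1253	Inverted	0	81	0.14	0.014
4	31730	33237	1508	1996	3467	1470	Direct	0	78	0.085	0.0085
5	96491	97215	725	67473	66715	759	Inverted	5.00e-166	78	0.25	0.029
6	96492	97219	728	13016	13789	772	Direct	4.00e-161	77	0.092	0.013
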