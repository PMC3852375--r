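clone	id	type	start	end	length	left_ltr_length	evalue	identity_pct	k	se_k	t_mya	se_t_mya
13d11E	1	Unknown	8721	14676	5956	1548	0	99	0.0065	0.0021	0.18	0.057
13d11E	2	Unknown	23393	29638	6246	1387	0	99	0.011	0.0028	0.30	0.079
13d11E	3	Gypsy	54004	70569	10886	715	0	99	0.0080	0.0057	0.22	0.16
13d11E	4	Unknown	58455	64134	5680	1450	0	96	0.027	0.0044	0.74	0.12
13d11E	5	Copia	74749	79514	4766	169	7e-65	93	0.045	0.017	1.2	0.48
13d11E	6	Copia	88141	92782	4642	208	5e-86	95	0.057	0.018	1.6	0.50
7a8D	7	Unknown	12651	32108	14093	366	4e-153	94	0.044	0.012	1.2	0.32
7a8D	8	Unknown	21888	27252	5365	1670	0	99	0.0030	0.0013	0.083	0.037
7a8D	9	Gypsy	36730	58367	12663	1538	0	97	0.022	0.0039	0.62	0.11
7a8D	10	Gypsy	45305	54279	7770	1345	0	97	0.024	0.0043	0.65	0.12
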