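chr	size_mb	n_markers	length_cm
GGA1	201	6800	491.2
GGA2	155	5073	318.8
GGA3	114	3924	269.3
GGA4	94	3143	183
GGA5	62	2112	170.1
GGA6	37	1595	98.8
GGA7	38	1627	103.9
GGA8	31	1330	107.4
GGA9	26	1115	90.2
GGA10	22.6	1247	77
GGA11	21.9	1172	77.2
GGA12	20.5	1252	94.1
GGA13	18.9	1090	76.8
GGA14	15.8	968	67.1
GGA15	13	993	65.9
GGA16	0.43	13	0.8
GGA17	11.2	830	66.8
GGA18	10.9	826	65
GGA19	9.9	779	62.8
GGA20	14	1346	75.2
GGA21	7	730	54.2
GGA22	3.9	285	47.4
GGA23	6	562	60.2
GGA24	6.4	659	60.6
GGA25	2.03	164	61.8
GGA26	5.1	601	57.5
GGA27	4.8	436	57.8
GGA28	4.5	503	55.5
LGE22	0.9	103	52
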