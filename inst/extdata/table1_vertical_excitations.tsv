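# Vertical excitation fixture for the Trp-[Re(CO)3(Dmp)(His)]+ chromophore
# (TDA-B3LYP reference data; transcribed by hand once, see package vignette).
# Energies E in eV, wavelengths in nm, oscillator strengths dimensionless,
# charge-transfer numbers in percent by hole->electron fragment pair.
# ct columns: hole_elec with fragments Trp, His, Dmp, ReCO3; "others" is the
# remainder not resolved into the named fragment pairs.
state	mult	idx	lambda_nm	E_eV	f_osc	ct_Trp_Trp	ct_Trp_Dmp	ct_Trp_ReCO3	ct_His_Dmp	ct_Dmp_Dmp	ct_ReCO3_Dmp	ct_ReCO3_ReCO3	ct_others	character
S1	1	1	457	2.71	0.001	0	92	5	0	1	0	0	1	CS
S2	1	2	438	2.83	0.011	1	96	1	0	1	0	0	0	CS
S3	1	3	385	3.22	0.003	0	3	0	12	5	71	6	3	MLCT
S4	1	4	379	3.27	0.011	0	79	4	1	8	6	0	2	CS
S5	1	5	365	3.39	0.007	1	93	1	1	4	0	0	0	CS
S6	1	6	360	3.44	0.008	0	6	0	8	13	69	2	2	MLCT
S7	1	7	347	3.57	0.064	0	0	0	3	5	82	7	2	MLCT
S8	1	8	344	3.60	0.107	0	2	0	4	10	75	6	3	MLCT
S9	1	9	332	3.73	0.042	0	1	0	2	18	77	1	1	MLCT
S10	1	10	329	3.77	0.000	0	1	0	84	2	4	0	9	LLCT
S11	1	11	321	3.86	0.003	0	0	0	0	5	93	1	1	MLCT
S12	1	12	312	3.97	0.016	0	1	0	76	13	8	1	2	LLCT
S13	1	13	307	4.04	0.003	1	86	8	1	2	0	0	1	CS
S14	1	14	303	4.09	0.002	0	4	0	14	60	16	2	4	IL
S15	1	15	294	4.21	0.001	0	10	73	0	0	0	2	13	AMCS
S16	1	16	292	4.25	0.003	0	6	0	1	76	13	0	3	IL
S17	1	17	289	4.28	0.032	0	0	1	1	1	9	72	15	MC
S18	1	18	286	4.33	0.001	0	0	1	0	1	9	71	17	MC
S19	1	19	282	4.39	0.001	0	0	0	2	3	20	62	12	MC
T1	3	1	459	2.70	0	1	89	5	0	3	0	0	1	CS
T2	3	2	444	2.79	0	3	90	0	0	6	0	0	0	CS
T3	3	3	414	2.99	0	0	11	0	2	56	26	2	2	IL
T4	3	4	409	3.03	0	0	15	1	1	54	22	2	4	IL
T5	3	5	392	3.16	0	0	11	0	6	28	47	5	3	MLCT
T6	3	6	374	3.31	0	1	68	4	1	6	17	2	2	CS
T7	3	7	362	3.42	0	1	11	0	8	11	67	1	1	MLCT
T8	3	8	360	3.44	0	11	58	0	3	10	17	0	1	CS
T9	3	9	357	3.47	0	83	12	0	0	1	1	0	2	AC
T10	3	10	351	3.53	0	0	2	0	0	7	77	11	3	MLCT
T11	3	11	342	3.62	0	0	20	2	3	62	6	1	6	IL
T12	3	12	338	3.67	0	0	7	0	1	39	41	8	4	MLCT
T13	3	13	327	3.79	0	0	2	0	46	19	26	2	6	LLCT
T14	3	14	325	3.81	0	0	2	0	18	21	55	1	3	MLCT
T15	3	15	322	3.85	0	0	2	0	14	78	3	1	2	IL
T16	3	16	319	3.88	0	0	0	0	1	2	10	70	16	MC
T17	3	17	307	4.03	0	0	1	0	1	16	80	1	1	MLCT
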