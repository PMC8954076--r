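compound	site	label	PA	rd	rd_O	rd_C	rd_H
Bn	C15	BnAC15	14.2	0.013	0.021	0.005	0.006
Bn	C17	BnAC17	11.6	0.010	0.015	0.006	0.009
Bn	C2	BnAC2	15.0	0.011	0.014	0.007	0.009
Bn	C6	BnAC6	26.2	0.013	0.011	0.011	0.014
Bn	N16	BnAN16	23.3	0.036	0.059	0.014	0.022
IsoBn	C15	IsoBnAC15	15.2	0.011	0.012	0.007	0.010
IsoBn	C17	IsoBnAC17	11.4	0.008	0.008	0.008	0.008
IsoBn	C2	IsoBnAC2	15.0	0.011	0.012	0.010	0.012
IsoBn	C6	IsoBnAC6	26.2	0.011	0.010	0.008	0.013
IsoBn	N16	IsoBnAN16	23.7	0.021	0.031	0.014	0.012
Bd	C15	BdAC15	14.2	0.013	0.021	0.004	0.006
Bd	C17	BdAC17	11.6	0.008	0.008	0.007	0.009
Bd	C2	BdAC2	14.9	0.009	0.008	0.008	0.008
Bd	C5	BdAC5	25.8	0.021	0.018	0.016	0.023
Bd	C6	BdAC6	22.9	0.013	0.010	0.010	0.014
Bd	N16	BdAN16	23.2	0.034	0.054	0.013	0.022
IsoBd	C15	IsoBdAC15	12.9	0.012	0.013	0.009	0.012
IsoBd	C17	IsoBdAC17	10.8	0.007	0.005	0.008	0.007
IsoBd	C2	IsoBdAC2	14.3	0.013	0.023	0.005	0.005
IsoBd	C5	IsoBdAC5	17.6	0.070	0.035	0.013	0.098
IsoBd	C6	IsoBdAC6	26.7	0.070	0.031	0.010	0.099
IsoBd	N16	IsoBdAN16	20.8	0.061	0.099	0.015	0.046
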