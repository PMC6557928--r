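component	reaction	parameter	species	value
kinetics	R1	vmax	NA	1.5
kinetics	R1	km	c_ala	2.0
kinetics	R2	vmax	NA	1.2
kinetics	R2	km	c_gly	2.0
kinetics	R3	vmax	NA	0.8
kinetics	R3	km	c_gly	1.0
kinetics	R4	vmax	NA	1.5
kinetics	R4	km	c_pyr	0.5
kinetics	R5	vmax	NA	1.2
kinetics	R5	km	c_accoa	0.5
kinetics	R6	vmax	NA	2.0
kinetics	R6	km	c_acp	0.5
kinetics	R7	vmax	NA	0.6
kinetics	R7	km	c_pyr	0.5
kinetics	R8	vmax	NA	2.0
kinetics	R8	km	a_ac	1.0
kinetics	R9	vmax	NA	0.8
kinetics	R9	km	a_co2	0.5
kinetics	R9	km	a_h2	0.05
kinetics	R10	vmax	NA	2.5
kinetics	R10	km	a_accoa	0.5
kinetics	R10	km	a_h4spt	0.2
kinetics	R11	vmax	NA	0.9
kinetics	R11	km	a_ch3h4spt	0.5
kinetics	R11	km	a_cor	0.2
kinetics	R12	vmax	NA	2.0
kinetics	R12	km	a_ch3cor	0.3
kinetics	R12	km	a_com	0.2
kinetics	R13	vmax	NA	1.2
kinetics	R13	km	a_ch3com	0.4
kinetics	R13	km	a_cob	0.2
kinetics	R14	vmax	NA	2.0
kinetics	R14	km	a_hsfd	0.3
kinetics	R14	km	a_h2	0.05
kinetics	M15	vmax	NA	0.05
kinetics	M15	km	a_pep	1.0
kinetics	M16	vmax	NA	0.3
kinetics	M16	km	a_h2	0.1
kinetics	M17	vmax	NA	0.4
kinetics	M17	km	a_for	1.0
kinetics	M18	vmax	NA	1.0
kinetics	M18	km	a_adp	0.5
kinetics	T1	k	NA	0.5
kinetics	T2	k	NA	0.5
kinetics	T3	k	NA	0.3
kinetics	T4	k	NA	0.2
kinetics	T5	k	NA	0.02
kinetics	T6	k	NA	0.2
kinetics	T7	k	NA	0.25
kinetics	T8	k	NA	0.5
kinetics	T9	k	NA	0.2
kinetics	T10	k	NA	0.2
kinetics	T11	k	NA	0.1
kinetics	T12	k	NA	0.3
initial	NA	initial	m_gly	21.4
initial	NA	initial	m_ala	8.9
initial	NA	initial	m_pro	12.4
initial	NA	initial	m_ac	0
initial	NA	initial	m_for	0
initial	NA	initial	m_pyr	0
initial	NA	initial	m_co2	0
initial	NA	initial	m_nh3	0
initial	NA	initial	m_h2	1.0
initial	NA	initial	m_ch4	0
initial	NA	initial	m_co	0
initial	NA	initial	c_ala	0.1
initial	NA	initial	c_gly	0.1
initial	NA	initial	c_pyr	0.05
initial	NA	initial	c_ac	0.05
initial	NA	initial	c_accoa	0.02
initial	NA	initial	c_acp	0.02
initial	NA	initial	c_for	0.01
initial	NA	initial	c_nh3	0.01
initial	NA	initial	c_co2	0.01
initial	NA	initial	c_nad	1.0
initial	NA	initial	c_nadh	0.5
initial	NA	initial	c_coa	1.0
initial	NA	initial	c_pi	10.0
initial	NA	initial	c_adp	1.0
initial	NA	initial	c_atp	2.0
initial	NA	initial	c_trxred	1.0
initial	NA	initial	c_trxox	0.5
initial	NA	initial	c_h2o	50.0
initial	NA	initial	c_h	0.1
initial	NA	initial	c_aladh	1.0
initial	NA	initial	c_aadh	1.0
initial	NA	initial	c_glyr	1.0
initial	NA	initial	c_pta	1.0
initial	NA	initial	c_ack	1.0
initial	NA	initial	a_ac	0.05
initial	NA	initial	a_accoa	0.02
initial	NA	initial	a_h4spt	1.0
initial	NA	initial	a_ch3h4spt	0.05
initial	NA	initial	a_co	0.01
initial	NA	initial	a_co2	0.1
initial	NA	initial	a_cor	0.5
initial	NA	initial	a_ch3cor	0.02
initial	NA	initial	a_com	0.5
initial	NA	initial	a_ch3com	0.02
initial	NA	initial	a_cob	0.5
initial	NA	initial	a_hsfd	0.05
initial	NA	initial	a_ch4	0.01
initial	NA	initial	a_h2	0.05
initial	NA	initial	a_for	0.01
initial	NA	initial	a_atp	2.0
initial	NA	initial	a_adp	1.0
initial	NA	initial	a_amp	0.5
initial	NA	initial	a_ppi	0.5
initial	NA	initial	a_coa	1.0
initial	NA	initial	a_pi	10.0
initial	NA	initial	a_h2o	50.0
initial	NA	initial	a_h	0.1
initial	NA	initial	a_fdox	1.0
initial	NA	initial	a_fdred	0.5
initial	NA	initial	a_f420	1.0
initial	NA	initial	a_f420h2	0.5
initial	NA	initial	a_pep	1.0
initial	NA	initial	a_so3	0.5
initial	NA	initial	a_na	1.0
initial	NA	initial	a_acs	1.0
initial	NA	initial	a_codh	1.0
initial	NA	initial	a_acds	1.0
initial	NA	initial	a_mt1	1.0
initial	NA	initial	a_mt2	1.0
initial	NA	initial	a_mcr	1.0
initial	NA	initial	a_hdr	1.0
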