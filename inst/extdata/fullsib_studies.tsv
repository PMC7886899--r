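trait	study	n_pair	c2	c2_se	h2	h2_se
height	biobank_study	19954	0.23	0.06	0.60	0.12
height	young	64847	0.07	0.05	0.68	0.10
height	hemani	20240	0.08	0.07	0.69	0.14
bmi	biobank_study	19885	-0.13	0.08	0.81	0.17
bmi	young	56461	0.08	0.06	0.39	0.12
bmi	hemani	20240	0.10	0.08	0.42	0.17
ea	biobank_study	19736	0.22	0.08	0.14	0.16
ea	young	32542	0.16	0.07	0.40	0.15
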