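SEX	AGE_LO	AGE_HI	PROPORTION	CUM_INCIDENCE
male	20	40	0.17	0.02
male	40	60	0.17	0.05
male	60	80	0.15	0.09
female	20	40	0.16	0.04
female	40	60	0.18	0.10
female	60	80	0.17	0.17
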