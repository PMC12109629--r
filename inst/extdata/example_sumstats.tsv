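variant_id	effect_allele	other_allele	eaf	beta	se	pval	n
rs0001	A	G	0.21	0.152	0.012	6.2e-37	7174
rs0002	c	t	0.35	-0.121	0.011	3.1e-28	7174
rs0003	A	T	0.50	0.098	0.013	4.6e-14	7174
rs0004	G	A	0.12	0.143	0.018	2.0e-15	7174
rs0005	T	C	0.28	0.001	0	0.52	7174
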