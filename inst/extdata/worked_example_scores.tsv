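probe_id	gene_symbol	GSE21510S2-3	GSE41258S2-3	GSE21510S4	GSE41258S4	GSE49355S4	printed_total	printed_rank	exact_sum
201637_s_at	FXR1	1	0	0	0	0	1	1000	1
203256_at	CDH3	0.6174	1	0	0.9400	0.9983	3.5557	25	1
37892_at	COL11A1	0.9990	0.8303	0	1	0.4707	3.3000	64	1
206976_s_at	HSPH1	0.3651	0.9524	0	0	1	2.3175	262	1
216230_x_at	SMPD1	-0.6184	-0.8424	-1	0	0	-2.4608	222	1
203908_at	SLC4A4	-0.9933	-0.9847	0	-0.9895	-0.9883	-3.9557	1	0
207502_at	GUCA2B	-0.9904	-0.9973	0	-0.9797	-0.9826	-3.9500	2	1
207003_at	GUCA2A	-0.9627	-0.9989	0	-0.9822	-0.9513	-3.8951	3	1
205480_s_at	UGP2	-0.9912	-0.9732	0	-0.9197	-0.9996	-3.8836	4	0
205950_s_at	CA1	-0.9974	-0.8872	0	-0.9959	-0.9352	-3.8159	5	0
212942_s_at	KIAA1199	0.9472	0.9962	0	0.8775	0.9926	3.8135	6	1
203961_at	NEBL	0.9788	0.9639	0	0.8508	0.9887	3.7821	7	0
219909_at	MMP28	-0.9332	-0.9995	0	-0.8856	-0.9613	-3.7796	8	1
213766_x_at	GNA11	-0.9973	-0.9037	0	-0.9059	-0.9609	-3.7677	9	0
202370_s_at	CBFB	0.9886	0.8933	0	0.9335	0.9522	3.7676	10	1
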