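gene	log2fc_nr_vs_sr	fold_printed	enriched_in	p	fdr
CALU	-1.047	2.07	SR	2.6e-05	0.037
SERPINE1	-1.144	2.21	SR	2.8e-05	0.037
CTSW	-0.735	1.66	SR	1.6e-04	0.068
RAP1B/RAP1A	-0.700	1.62	SR	2.3e-04	0.068
ANGPT1	-0.748	1.68	SR	2.4e-04	0.068
ARHGAP35	-1.587	3	SR	6.8e-04	0.091
FKBP4	-0.945	1.92	SR	7.4e-04	0.091
FHOD1	-0.794	1.73	SR	7.5e-04	0.091
B4GALT7	-0.979	1.97	SR	8.7e-04	0.094
CNDP1	-0.713	1.64	SR	9.9e-04	0.094
PIN1	-1.158	2.23	SR	1.2e-03	0.094
TCN2	-0.700	1.62	SR	1.6e-03	0.096
AGER	0.968	1.96	NR	5.4e-05	0.048
DEFA1/DEFA3	1.147	2.21	NR	4.1e-04	0.078
ITPA	0.826	1.77	NR	6.5e-04	0.091
BPIFB2	1.419	2.67	NR	1.0e-03	0.094
UPB1	0.806	1.75	NR	1.2e-03	0.094
ADM	0.689	1.61	NR	1.3e-03	0.094
RACK1	1.067	2.09	NR	1.4e-03	0.095
STXBP5	0.897	1.86	NR	1.4e-03	0.095
LSM1	0.922	1.89	NR	1.5e-03	0.095
OLR1	1.125	2.18	NR	1.7e-03	0.096
CTSG	0.973	1.96	NR	1.7e-03	0.096
CD300A	0.900	1.86	NR	1.7e-03	0.096
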