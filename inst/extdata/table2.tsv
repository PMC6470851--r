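seq1	seq2	ka	ks	kaks	date_mya	dup_type
OsSTP10	OsSTP18	0.3290306	0.5779125	0.5693432	18.078602	segmental
OsERD3	OsERD5	0.1951074	1.1448128	0.1704273	10.720185	segmental
OsSTP11	OsSTP12	0.0328413	0.1013588	0.3240102	1.8044666	tandem
OsSTP8	OsSTP7	0.0615979	0.1135565	0.542443	3.3845026	tandem
OsPLT11	OsPLT12	0.0777016	0.1552719	0.5004226	4.2693165	tandem
OsERD3	OsERD4	0.0837405	0.5136912	0.1630172	4.6011267	tandem
OsPLT8	OsPLT9	0.142104	0.3454965	0.4113038	7.807912	tandem
OsPLT5	OsPLT6	0.1481074	0.3072356	0.4820647	8.1377715	tandem
OsPLT1	OsPLT7	0.1914638	0.3353385	0.5709568	10.51999	tandem
OsSTP14	OsSTP1	0.1975753	0.3867837	0.5108159	10.855785	tandem
OsERD1	OsERD2	0.2101177	0.9200798	0.228369	11.54493	tandem
OsSTP1	OsSTP15	0.3065527	0.4261786	0.7193058	16.843556	tandem
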