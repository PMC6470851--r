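gene_id	locus_tag	subfamily
OsAZT1	LOC_Os02g13560.1	AZT
OsAZT2	LOC_Os02g58530.1	AZT
OsAZT3	LOC_Os03g03680.1	AZT
OsAZT4	LOC_Os10g39440.2	AZT
OsAZT5	LOC_Os11g28610.1	AZT
OsAZT6	LOC_Os11g40540.2	AZT
OsERD1	LOC_Os03g24860.1	ERD
OsERD2	LOC_Os03g24870.1	ERD
OsERD3	LOC_Os05g49260.1	ERD
OsERD4	LOC_Os05g49270.1	ERD
OsERD5	LOC_Os05g50280.1	ERD
OsERD6	LOC_Os11g42430.1	ERD
OsINT1	LOC_Os04g41460.1	INT
OsINT2	LOC_Os07g05640.1	INT
OsINT3	LOC_Os04g43210.1	INT
OsSTP1	LOC_Os04g37980.1	STP
OsSTP10	LOC_Os02g36414.1	STP
OsSTP11	LOC_Os02g36440.1	STP
OsSTP12	LOC_Os02g36450.1	STP
OsSTP13	LOC_Os03g01170.1	STP
OsSTP14	LOC_Os04g37970.1	STP
OsSTP15	LOC_Os04g37990.1	STP
OsSTP16	LOC_Os04g38010.1	STP
OsSTP17	LOC_Os04g38026.1	STP
OsSTP18	LOC_Os04g38220.1	STP
OsSTP19	LOC_Os06g04900.1	STP
OsSTP2	LOC_Os03g39710.1	STP
OsSTP20	LOC_Os07g03910.1	STP
OsSTP21	LOC_Os07g03960.1	STP
OsSTP22	LOC_Os07g10590.1	STP
OsSTP23	LOC_Os09g09520.1	STP
OsSTP24	LOC_Os09g12590.1	STP
OsSTP25	LOC_Os09g15330.1	STP
OsSTP26	LOC_Os09g24924.1	STP
OsSTP27	LOC_Os10g41190.1	STP
OsSTP28	LOC_Os11g38160.1	STP
OsSTP3	LOC_Os07g01560.1	STP
OsSTP4	LOC_Os03g11900.1	STP
OsSTP5	LOC_Os08g08070.1	STP
OsSTP6	LOC_Os07g37320.1	STP
OsSTP7	LOC_Os01g38680.1	STP
OsSTP8	LOC_Os01g38670.1	STP
OsSTP9	LOC_Os02g06540.1	STP
OspGlcT1	LOC_Os01g04190.2	pGlcT
OspGlcT2	LOC_Os02g17500.1	pGlcT
OspGlcT3	LOC_Os09g23110.1	pGlcT
OspGlcT4	LOC_Os09g27900.1	pGlcT
OsPLT1	LOC_Os03g10090.1	PLT
OsPLT10	LOC_Os11g41830.1	PLT
OsPLT11	LOC_Os11g41840.1	PLT
OsPLT12	LOC_Os11g41850.1	PLT
OsPLT13	LOC_Os11g41870.1	PLT
OsPLT14	LOC_Os12g32760.1	PLT
OsPLT15	LOC_Os12g32940.1	PLT
OsPLT2	LOC_Os01g73590.1	PLT
OsPLT3	LOC_Os10g21590.1	PLT
OsPLT4	LOC_Os04g44750.1	PLT
OsPLT5	LOC_Os07g39350.1	PLT
OsPLT6	LOC_Os07g39360.1	PLT
OsPLT7	LOC_Os03g10100.1	PLT
OsPLT8	LOC_Os04g58220.1	PLT
OsPLT9	LOC_Os04g58230.1	PLT
OsXTPH1	LOC_Os03g60820.1	XTPH
OsXTPH2	LOC_Os10g42830.1	XTPH
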