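symbol	chrom	start	end	strand	gene_class	host_of	gene_sets
ERG	21	38380027	38663026	-	protein_coding		ETS_family
TMPRSS2	21	41464300	41507799	-	protein_coding		androgen_response
SLC45A3	1	205630000	205651999	-	protein_coding		androgen_response
ELK4	1	205588000	205616999	-	protein_coding		ETS_family
ETV1	7	13930000	14029999	-	protein_coding		ETS_family
ETV4	17	43527000	43545999	-	protein_coding		ETS_family
ETV5	3	185764000	185827999	-	protein_coding		ETS_family
FLI1	11	128556000	128682999	+	protein_coding		ETS_family
ELF3	1	202005000	202011299	+	protein_coding		ETS_family
TTC6	14	37575000	37844999	+	protein_coding	SNORD127	
MIPOL1	14	37243000	37572999	+	protein_coding		tumor_suppressor
RP11-356O9.1	14	37135000	37194999	+	lncRNA		
SLC25A21	14	36681000	37180999	-	protein_coding		
FSIP1	15	39490000	39729999	-	protein_coding		
RP11-624L4.1	15	39780000	39809999	+	lncRNA		
MBTPS2	X	21837000	21882999	+	protein_coding		
LL0XNC01-39B3.1	X	21900000	21916999	+	lncRNA		
SMS	X	21940000	21993999	+	protein_coding		androgen_response
AMACR	5	34000200	34021199	-	protein_coding		
C1QTNF3-AMACR	5	33968000	34020999	-	protein_coding		
C1QTNF3	5	33968000	33994999	-	protein_coding		
PTEN	10	87863000	87971999	+	protein_coding		tumor_suppressor
TP53	17	7668000	7693999	-	protein_coding		tumor_suppressor
FOXP1	3	70954000	71583999	-	protein_coding		tumor_suppressor
RB1	13	48303000	48481999	+	protein_coding		tumor_suppressor
NKX3-1	8	23678000	23682599	-	protein_coding		tumor_suppressor;androgen_response
KLK3	19	50854000	50859899	+	protein_coding		androgen_response
PMEPA1	20	57648000	57710999	-	protein_coding		androgen_response
FKBP5	6	35573000	35727999	-	protein_coding		androgen_response
NDRG1	8	133237000	133296999	-	protein_coding		androgen_response
PTPN12	7	77539000	77638999	+	protein_coding		
GSAP	7	77647000	77736999	+	protein_coding		
MAPKAPK5	12	111843000	111872999	+	protein_coding		
ACAD10	12	111881000	111920999	+	protein_coding		
ACPP	3	132317000	132366999	+	protein_coding		androgen_response
CPNE4	3	131530000	132229999	+	protein_coding		
SCHLAP1	2	180690000	180889999	+	lncRNA		
UBE2E3	2	181103000	181182999	+	protein_coding		
ZFHX3	16	72782000	73047999	-	protein_coding		tumor_suppressor
YME1L1	10	27110000	27154999	-	protein_coding		
THBS1	15	39581000	39596999	+	protein_coding		
AMBRA1	11	46396000	46595999	-	protein_coding		
CKAP5	11	46721000	46860999	-	protein_coding		
PRUNE2	9	76680000	76979999	-	protein_coding		
IQSEC1	3	12938000	13107999	-	protein_coding		
SCCPDH	1	246700000	246739999	+	protein_coding		
GPATCH8	17	44490000	44569999	-	protein_coding		
PYY	17	43952000	43953199	+	protein_coding		
RNLS	10	88300000	88609999	-	protein_coding		
PDZRN3	3	73425000	73664999	-	protein_coding		
EIF4E3	3	71720000	71779999	-	protein_coding		
SKIV2L2	5	54647000	54756999	-	protein_coding		
PLPP1	5	55391000	55480999	+	protein_coding		
KCTD1	18	26452000	26681999	-	protein_coding		
SNORD127	14	37702000	37702089	+	snoRNA		
SNORD3A	17	19189000	19189216	+	snoRNA		
SNORD17	20	39867000	39867236	+	snoRNA		
SNORA31	13	27251000	27251129	+	snoRNA		
SNORD116-1	15	24978000	24978096	+	snoRNA		
RNU4-2	12	120291000	120291140	+	snRNA		
RNU1-1	1	16895000	16895163	-	snRNA		
RNU5A-1	15	65304000	65304115	+	snRNA		
RNU12	22	42615000	42615149	-	snRNA		
GAS5	1	173863000	173868199	-	lncRNA	SNORD44;SNORD47	
SNORD44	1	173866000	173866096	-	snoRNA		
SNORD47	1	173867000	173867069	-	snoRNA		
RPL13A	19	49487000	49491899	+	protein_coding	SNORD32A;SNORD33	
SNORD32A	19	49488500	49488585	+	snoRNA		
SNORD33	19	49489400	49489486	+	snoRNA		
RP11-599B13.3	7	14010000	14034999	+	lncRNA		
RP11-597A11.1	6	26180000	26191999	+	lncRNA		
RP11-380G5.4	10	88100000	88108999	+	lncRNA		
CTC-340A15.2	5	140100000	140114999	+	lncRNA		
AC004158.2	16	73090000	73097999	-	lncRNA		
GENE001	5	15672105	15883838	-	protein_coding		
GENE002	3	86376844	86485524	-	protein_coding		
GENE003	13	56643535	56810902	+	protein_coding		
GENE004	20	173998135	174055613	+	protein_coding		
GENE005	9	84225414	84358066	+	protein_coding		
GENE006	14	201390272	201679050	-	protein_coding		
GENE007	19	35070993	35274441	+	protein_coding		androgen_response
GENE008	11	191777567	191904431	-	protein_coding		
GENE009	21	227646250	227924210	-	protein_coding		
GENE010	5	189995799	190152093	-	protein_coding		
GENE011	17	161612957	161851592	+	protein_coding		
GENE012	X	213615058	213693250	+	protein_coding		
GENE013	17	179637954	179744502	-	protein_coding		
GENE014	17	113045824	113247466	-	protein_coding		
GENE015	21	101088033	101349504	+	protein_coding		
GENE016	21	60626014	60808580	+	protein_coding		
GENE017	9	76909996	77138082	-	protein_coding		
GENE018	X	82704131	82738912	+	protein_coding		
GENE019	2	234027986	234287539	+	protein_coding		
GENE020	21	198911879	199092457	+	protein_coding		
GENE021	12	145096310	145350629	+	protein_coding		
GENE022	X	145165060	145362190	+	protein_coding		androgen_response
GENE023	2	77341123	77515488	-	protein_coding		androgen_response
GENE024	9	29789056	30031682	-	protein_coding		
GENE025	6	28801099	28825651	-	protein_coding		
GENE026	4	3041727	3313321	+	protein_coding		
GENE027	17	66316377	66387286	+	protein_coding		androgen_response
GENE028	12	104984870	105031155	+	protein_coding		
GENE029	5	65307052	65314899	+	protein_coding		
GENE030	5	63542108	63756969	+	protein_coding		
GENE031	2	92242741	92403093	+	protein_coding		
GENE032	19	129328713	129392001	+	protein_coding		
GENE033	22	221990518	222144302	-	protein_coding		
GENE034	15	84227168	84466514	+	protein_coding		
GENE035	3	42792208	42910620	-	protein_coding		
GENE036	8	138560265	138724810	+	protein_coding		
GENE037	9	88640186	88667625	-	protein_coding		
GENE038	16	181511439	181537688	+	protein_coding		
GENE039	21	44099652	44235883	-	protein_coding		
GENE040	2	135084566	135203082	+	protein_coding		
GENE041	11	66077509	66357551	-	protein_coding		
GENE042	12	217001504	217205207	+	protein_coding		
GENE043	15	238443179	238620414	+	protein_coding		
GENE044	17	142486868	142547863	+	protein_coding		
GENE045	6	12593383	12609878	-	protein_coding		
GENE046	16	97415452	97456424	-	protein_coding		
GENE047	15	236658191	236681740	+	protein_coding		
GENE048	1	28819319	28865070	-	protein_coding		
GENE049	18	36402448	36436266	-	protein_coding		
GENE050	12	22441365	22718287	-	protein_coding		
GENE051	15	30064562	30299340	+	protein_coding		
GENE052	12	204656842	204742785	+	protein_coding		
GENE053	3	21119577	21411791	+	protein_coding		
GENE054	11	123074660	123131225	-	protein_coding		
GENE055	7	164805225	164997687	-	protein_coding		
GENE056	6	111916972	111950597	-	protein_coding		androgen_response
GENE057	6	178753495	178921297	-	protein_coding		androgen_response
GENE058	6	71797578	71809888	-	protein_coding		
GENE059	14	25153298	25297719	+	protein_coding		
GENE060	X	186909623	186993589	-	protein_coding		
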