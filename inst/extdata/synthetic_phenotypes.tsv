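id	population	sire	dam	sex	litter	pen	cg	dam_line	parity	age	cIMF	cCDG	pLBF
DS0001	PB_SIRE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
DS0002	PB_SIRE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
DS0003	PB_SIRE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
DD0001	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
DD0002	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
DD0003	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
LS0001	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
LS0002	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
LS0003	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
LD0001	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
LD0002	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
LD0003	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
LD0004	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
LD0005	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
YS0001	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
YS0002	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
YS0003	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
YD0001	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
YD0002	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
YD0003	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
YD0004	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
YD0005	ANCESTOR	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
PB0001	PB	DS0001	DD0001	M	L_DD0001	PBP_M001	PBG01	NA	2	183.4	NA	NA	13.5433489135061
PB0002	PB	DS0001	DD0001	M	L_DD0001	PBP_M001	PBG01	NA	3	177.7	NA	NA	10.3833159438582
PB0003	PB	DS0001	DD0001	F	L_DD0001	PBP_F001	PBG01	NA	3	183.7	NA	NA	18.6336925549407
PB0004	PB	DS0001	DD0001	M	L_DD0001	PBP_M001	PBG01	NA	4	184	NA	NA	12.0910805137327
PB0005	PB	DS0001	DD0001	F	L_DD0001	PBP_F001	PBG01	NA	4	181.5	NA	NA	12.6121128403468
PB0006	PB	DS0001	DD0001	M	L_DD0001	PBP_M001	PBG01	NA	4	171.9	NA	NA	16.0155706757081
PB0007	PB	DS0003	DD0002	M	L_DD0002	PBP_M001	PBG01	NA	2	179.3	NA	NA	19.9583725163473
PB0008	PB	DS0003	DD0002	F	L_DD0002	PBP_F001	PBG01	NA	3	183.1	NA	NA	18.7927931692452
PB0009	PB	DS0003	DD0002	F	L_DD0002	PBP_F001	PBG01	NA	2	183.5	NA	NA	5.38970255451238
PB0010	PB	DS0003	DD0002	F	L_DD0002	PBP_F001	PBG01	NA	4	179.4	NA	NA	18.435549084027
PB0011	PB	DS0003	DD0002	F	L_DD0002	PBP_F001	PBG01	NA	3	182.4	NA	NA	15.1766860793925
PB0012	PB	DS0003	DD0002	M	L_DD0002	PBP_M001	PBG01	NA	1	178.7	NA	NA	12.6475522415014
PB0013	PB	DS0002	DD0003	F	L_DD0003	PBP_F001	PBG01	NA	2	178.9	NA	NA	15.3625550302592
PB0014	PB	DS0002	DD0003	M	L_DD0003	PBP_M001	PBG01	NA	1	180.7	NA	NA	11.3896995957829
PB0015	PB	DS0002	DD0003	M	L_DD0003	PBP_M001	PBG01	NA	1	180.1	NA	NA	12.1732006359332
PB0016	PB	DS0002	DD0003	M	L_DD0003	PBP_M001	PBG01	NA	3	179.1	NA	NA	15.9886305601229
PB0017	PB	DS0002	DD0003	M	L_DD0003	PBP_M001	PBG01	NA	2	175.3	NA	NA	16.3261634393797
PB0018	PB	DS0002	DD0003	M	L_DD0003	PBP_M001	PBG01	NA	1	181.5	NA	NA	17.7814822939345
F10007	DAM	YS0001	LD0004	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
F10006	DAM	YS0003	LD0003	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
F10008	DAM	YS0003	LD0003	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
F10009	DAM	YS0003	LD0002	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
F10001	DAM	LS0002	YD0002	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
F10003	DAM	LS0001	YD0002	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
F10005	DAM	LS0002	YD0003	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
F10004	DAM	LS0002	YD0004	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
F10002	DAM	LS0003	YD0005	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
CB0025	CB	DS0003	F10007	F	L_F10007	CBP_F002	CBG02	YL	NA	NA	2.65290376310602	0.694955675309708	NA
CB0026	CB	DS0003	F10007	F	L_F10007	CBP_F003	CBG03	YL	NA	NA	3.52837452501004	0.513461772502908	NA
CB0027	CB	DS0003	F10007	M	L_F10007	CBP_M002	CBG02	YL	NA	NA	3.34593285999387	0.696820649490656	NA
CB0028	CB	DS0003	F10007	F	L_F10007	CBP_F003	CBG03	YL	NA	NA	2.90951615918431	0.502733946341586	NA
CB0021	CB	DS0003	F10006	M	L_F10006	CBP_M002	CBG02	YL	NA	NA	0.071279746683582	0.505461852650123	NA
CB0022	CB	DS0003	F10006	F	L_F10006	CBP_F002	CBG02	YL	NA	NA	3.43934176379276	0.524475462196257	NA
CB0023	CB	DS0003	F10006	M	L_F10006	CBP_M002	CBG02	YL	NA	NA	2.24063361770431	0.448111070826025	NA
CB0024	CB	DS0003	F10006	F	L_F10006	CBP_F002	CBG02	YL	NA	NA	0.963359352721728	0.492453359401135	NA
CB0029	CB	DS0002	F10008	M	L_F10008	CBP_M001	CBG01	YL	NA	NA	4.61139152631176	0.531363779339379	NA
CB0030	CB	DS0002	F10008	M	L_F10008	CBP_M001	CBG01	YL	NA	NA	3.20830490990196	0.594354699592883	NA
CB0031	CB	DS0002	F10008	F	L_F10008	CBP_F002	CBG02	YL	NA	NA	2.42093969869291	0.527466088745568	NA
CB0032	CB	DS0002	F10008	F	L_F10008	CBP_F002	CBG02	YL	NA	NA	2.75086376322217	0.59802561784197	NA
CB0033	CB	DS0001	F10009	F	L_F10009	CBP_F001	CBG01	YL	NA	NA	4.26973710462794	0.511469988463662	NA
CB0034	CB	DS0001	F10009	M	L_F10009	CBP_M001	CBG01	YL	NA	NA	4.41579043898675	0.473446330573024	NA
CB0035	CB	DS0001	F10009	M	L_F10009	CBP_M001	CBG01	YL	NA	NA	3.26157151874644	0.447746163410806	NA
CB0036	CB	DS0001	F10009	F	L_F10009	CBP_F001	CBG01	YL	NA	NA	2.99897566296955	0.589631396073619	NA
CB0001	CB	DS0001	F10001	M	L_F10001	CBP_M001	CBG01	LY	NA	NA	3.72154674916878	0.52460052825161	NA
CB0002	CB	DS0001	F10001	F	L_F10001	CBP_F001	CBG01	LY	NA	NA	NA	0.539237847353456	NA
CB0003	CB	DS0001	F10001	F	L_F10001	CBP_F001	CBG01	LY	NA	NA	3.36365800564645	0.598075807183041	NA
CB0004	CB	DS0001	F10001	M	L_F10001	CBP_M001	CBG01	LY	NA	NA	3.76237346942685	0.5099998008358	NA
CB0009	CB	DS0001	F10003	F	L_F10003	CBP_F001	CBG01	LY	NA	NA	3.49771322186465	0.476655462875116	NA
CB0010	CB	DS0001	F10003	F	L_F10003	CBP_F001	CBG01	LY	NA	NA	NA	0.503610179373143	NA
CB0011	CB	DS0001	F10003	M	L_F10003	CBP_M001	CBG01	LY	NA	NA	2.86038490231923	0.61773174185025	NA
CB0012	CB	DS0001	F10003	F	L_F10003	CBP_F001	CBG01	LY	NA	NA	2.60497603367136	0.419814680201794	NA
CB0017	CB	DS0002	F10005	F	L_F10005	CBP_F001	CBG01	LY	NA	NA	3.21981262675205	0.523065416004911	NA
CB0018	CB	DS0002	F10005	M	L_F10005	CBP_M001	CBG01	LY	NA	NA	2.69844397107774	0.511035522669238	NA
CB0019	CB	DS0002	F10005	F	L_F10005	CBP_F001	CBG01	LY	NA	NA	3.88513723745891	0.447679016282343	NA
CB0020	CB	DS0002	F10005	F	L_F10005	CBP_F002	CBG02	LY	NA	NA	1.59051409886299	0.520833748019207	NA
CB0013	CB	DS0002	F10004	F	L_F10004	CBP_F001	CBG01	LY	NA	NA	2.89679345901018	0.383089862480257	NA
CB0014	CB	DS0002	F10004	F	L_F10004	CBP_F001	CBG01	LY	NA	NA	2.64148860180313	0.422664174928399	NA
CB0015	CB	DS0002	F10004	M	L_F10004	CBP_M001	CBG01	LY	NA	NA	2.94903523125919	0.533953169533206	NA
CB0016	CB	DS0002	F10004	M	L_F10004	CBP_M001	CBG01	LY	NA	NA	2.92042684296959	0.450416004872171	NA
CB0005	CB	DS0003	F10002	M	L_F10002	CBP_M001	CBG01	LY	NA	NA	2.81712089782508	0.599083461224463	NA
CB0006	CB	DS0003	F10002	F	L_F10002	CBP_F002	CBG02	LY	NA	NA	NA	0.531583328483375	NA
CB0007	CB	DS0003	F10002	F	L_F10002	CBP_F002	CBG02	LY	NA	NA	2.74822664916463	0.594858627291925	NA
CB0008	CB	DS0003	F10002	F	L_F10002	CBP_F002	CBG02	LY	NA	NA	1.31676477195487	0.53967010202055	NA
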