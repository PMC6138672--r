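protein_id	gene	sequence	kind	tm	nglyc	printed_gp	printed_hph	source_table	intact
Q9UM22	EPDR1	MPGRAPLRTVPGALGAWLLGGLWAWTLCGLCSLGAVG	SP	FALSE	TRUE	29.7	0.727	1	TRUE
Q9H6X2	ANTXR1	MATAERRALGIGFQWLSLATLVLICAG	SP	TRUE	TRUE	15.6	0.262	1	FALSE
Q8IWB1	ITPRIP	MAMGLFRVCLVVVTA	SP	FALSE	TRUE	6.7	1.951	1	TRUE
O00622	CYR61	MSSRIARALALVVTLLHLTRLALS	SP	FALSE	FALSE	0.0	1.017	1	TRUE
P54802	NAGLU	MEAVAVAAAVGVLLLAGAGGAAG	SP	FALSE	TRUE	21.7	1.461	1	TRUE
Q9GZX9	TWSG1	MKLHYVAVLTLAILMFLTWLPESLS	SP	FALSE	TRUE	4.0	1.269	1	TRUE
Q13454	TUSC3	MGARGAPSRRRQAGRRLRYLPTGSFPFLLLLLLLCIQLGGG	SP	TRUE	FALSE	24.4	-0.01	1	TRUE
Q9Y3A6	TMED5	MGDKIWLPFPVLLLAALPPVLLPGAAG	SP	TRUE	FALSE	29.6	1.074	1	TRUE
Q9H0U3	MAGT1	MAARWRFWCVSVTMVVALLIVCDVPSASA	SP	TRUE	TRUE	3.5	1.227	1	FALSE
Q13214	SEMA3B	MGRAGAAAVIPGLALLWAVGLGSA	SP	FALSE	TRUE	25.0	1.106	1	TRUE
Q9BRR6	ADPGK	MALWRGSAYAGFLALAVGCVFL	SP	FALSE	FALSE	13.6	1.356	1	TRUE
P02751	FN1	MLRGPGPGLLLLAVQCLGTAVPSTGA	SP	FALSE	TRUE	25.8	0.161	1	FALSE
P45877	PPIC	MGPGPRLLLPLVLCVGLGALVFSSGAEG	SP	FALSE	TRUE	32.1	1.063	1	TRUE
Q9UMX5	NENF	MVGPAPRRRLRPLAALALVLALAPGLPTARA	SP	FALSE	FALSE	22.6	0.281	1	TRUE
O14773	TPP1	MGLQACLLGLFALILSGKCSY	SP	FALSE	TRUE	15.8	1.526	1	FALSE
P15941	MUC1	MTPGTQSPFFLLLLLTVLTVVTG	SP	TRUE	TRUE	17.4	1.31	1	TRUE
Q15582	TGFBI	MALFVRLLALALALALGPAATLA	SP	FALSE	FALSE	8.7	1.729	1	TRUE
O75629	CREG1	MAGLSRGSARALLAALLASTLLALLVSPARG	SP	FALSE	TRUE	12.9	0.88	1	TRUE
Q9ULF5	SLC39A10	MKVHMHTKFCLICLLTFIFHHCNHC	SP	TRUE	TRUE	0.0	0.707	1	TRUE
Q08380	LGALS3BP	MTPPRLFWVWLLVAGTQG	SP	FALSE	TRUE	22.2	0.523	1	TRUE
P08069	IGF1R	MKSGSGGGSPTSLWGLLFLSAALSLWPTSG	SP	TRUE	TRUE	26.7	0.404	1	TRUE
P08572	COL4A2	MGRDQRAVAGPALRRWLLLGTVTVGFLAQSVLA	SP	FALSE	TRUE	20.0	-0.04	1	FALSE
Q8N2U0	TMEM256	MAGPAAAFRRLGALSGAAALGFASYGAHG	SP	TRUE	FALSE	24.1	0.292	1	TRUE
Q9UBV2	SEL1L	MRVRIGLTLLLCAVLLSLASA	SP	TRUE	TRUE	4.8	1.651	1	TRUE
Q969V3	NCLN	MLEEAGEVLENMLKASCLPLGFIVFLPAVLLLVAPPLPAADA	SP	TRUE	TRUE	16.7	1.038	1	TRUE
O14672	ADAM10	MVLLRVLILLLSWAAGMG	SP	TRUE	TRUE	15.8	1.775	1	FALSE
P11117	ACP2	MAGKRSGWSRAALLQLLLGVNLVVMPPTRA	SP	TRUE	TRUE	16.7	0.304	1	TRUE
P06756	ITGAV	MAFPPRRRLRLGPRGLPLLLSGLLLPLCRA	SP	TRUE	TRUE	29.7	0.163	1	FALSE
Q12907	LMAN2	MAAEGWIWRWGWGRRCLGRPGLLGPGPGPTTPLFLLLLLGSVTA	SP	TRUE	TRUE	31.8	0.23	1	TRUE
P56937	HSD17B7	MRKVVLITGASSGIGLALCKRL	SP	TRUE	TRUE	19.1	1.733	1	FALSE
P39656	DDOST	MGYFRCARAGSFGRRRKMEPSTAARAWALFWLLLPLLGAVCA	SP	TRUE	FALSE	14.3	0.115	1	TRUE
Q8TB61	SLC35B2	MDARWWAVVVLAAFPSLGAG	SP	TRUE	FALSE	23.8	0.627	1	FALSE
Q6PIU2	NCEH1	MRSSCVLLTALVALA	SP	FALSE	TRUE	14.3	1.617	1	FALSE
Q5JPE7	NOMO2	MLVGQGAGLLGPAVVTAAVVLLLSGVGPAHG	SP	TRUE	TRUE	29.0	1.259	1	TRUE
P08236	GUSB	MARGSAVAWAALGPLLWGCALG	SP	FALSE	TRUE	22.7	0.883	1	TRUE
P00533	EGFR	MRPSGTAGAALLALLAALCPASRA	SP	TRUE	TRUE	16.7	0.634	1	TRUE
Q5VW38	GPR107	MAALAPVGSPASRGPRLAAGLRLLPMLGLLQLLAEPGLG	SP	FALSE	TRUE	28.2	0.538	1	TRUE
Q8N129	CNPY4	MGPVRLGILLFLFLAVHEAWA	SP	FALSE	FALSE	14.3	1.312	1	TRUE
O15121	DEGS1	IKSLMKPDPNLIWIIIMMVLTQLGAFYIVKKDLDWKWVIF	TMH	TRUE	FALSE	9.5	1.801	2	NA
Q99519	NEU1	LPDRRWGPRILGFWGGCRVWVFAAIFLLLSLAASWSKAENDFG	TMH	TRUE	TRUE	17.0	0.193	2	NA
P61803	DAD1	STPQRLKLLDAYLLYILLTGALQFGYCLLVGTFPFNSFLSGFI	TMH	TRUE	FALSE	14.3	1.662	2	NA
P04920	SLC4A2	DFRDALDPQCLAAVIFIYFAALSPAITFGGLLGEKTQDLIGVS	TMH	TRUE	TRUE	16.7	1.791	2	NA
P41221	WNT5A	GMAGSAMSSKFFLVALAIFFSFAQVVIEANSWWSLGMNNPVQM	TMH	TRUE	TRUE	14.3	1.135	2	NA
Q68CQ7	GLT8D1	MSFRKVNIIILVLAVALFLLVLHHNFLSLSSLLR	TMH	TRUE	TRUE	0.0	2.386	2	NA
Q15629	TRAM1	LQNHADIVSCVAMVFLLGLMFEITAKASIIFVTLQYNVTLPAT	TMH	TRUE	TRUE	4.8	1.888	2	NA
P55061	TMBIM6	TPSTQQHLKKVYASFALCMFVAAAGAYVHMVTHFIQAG	TMH	TRUE	FALSE	4.8	1.531	2	NA
Q5T9L3	WLS	GAIIENMSTKKLCIVGGILLVFQIIAFLVGGLIAPGPTTAVSY	TMH	TRUE	FALSE	19.1	1.23	2	NA
Q8TCJ2	STT3B	AGLSGGLSQPAGWQSLLSFTILFLAWLAGFSSRLFAVIRF	TMH	TRUE	TRUE	14.3	1.225	2	NA
Q6UW68	TMEM205	GNLGGLIKMVHLLVLSGAWGMQMWVTFVSGFLLFRSLPRHTFG	TMH	TRUE	FALSE	14.3	1.385	2	NA
Q643R3	LPCAT4	HLSRLQRVKFCLLGALLAPIRVLLAFIVLFLLWPFAWLQVAGL	TMH	TRUE	TRUE	8.7	2.387	2	NA
P35610	SOAT1	DELLEVDHIRTIYHMFIALLILFILSTLVVDYIDEGRLVLEFS	TMH	TRUE	FALSE	0.0	2.542	2	NA
Q9UIQ6	LNPEP	ACSVPSARTMVVCAFVIVVAVSVIMVIYLLPRCTFTKEGC	TMH	TRUE	TRUE	0.0	3.057	2	NA
P11166	SLC2A1	EPSSKKLTGRLMLAVGGAVLGSLQFGYNTGVINAPQKVIEEFY	TMH	TRUE	TRUE	22.7	1.196	2	NA
Q8TCT9	HM13	TTRPPSTPEGIALAYGSLLLMALLPIFFGALRSVRCARGKNAS	TMH	TRUE	TRUE	14.3	2.025	2	NA
Q15005	SPCS2	EKYKYVENFGLIDGRLTICTISCFFAIVALIWDYMHPFPESKP	TMH	TRUE	FALSE	4.8	1.516	2	NA
Q8NHP6	MOSPD2	KLEDQVQRCIWFQQLLLSLTMLLLAFVTSFFYLLYS	TMH	TRUE	FALSE	0.0	2.133	2	NA
Q9NW15	ANO10	IDSIRGYFGETIALYFGFLEYFTFALIPMAVIGLPYYLFVWED	TMH	TRUE	FALSE	9.5	1.736	2	NA
A0PJW6	TMEM223	VLLFEHDRGRFFTILGLFCAGQGVFWASMAVAAVSRPPVPV	TMH	TRUE	FALSE	14.3	1.531	2	NA
P08962	CD63	AVEGGMKCVKFLLYVLLLAFCACAVGLIAVGVGAQLVLSQT	TMH	TRUE	TRUE	9.52	2.491	2	NA
Q9BZH6	WDR11	CSPQVNQKSKALLVLLSLGCFFSVAETLHSMRYFDRAALFV	TMH	TRUE	FALSE	4.76	1.627	2	NA
Q9H173	SIl1	MAPQSLPSSRMAPLGMLLGLLMAACFTFCLS	SP	FALSE	TRUE	16.1	0.992	3	TRUE
P27797	CALR	MLLSVPLLLGLLGLAVA	SP	FALSE	TRUE	17.6	2.307	3	TRUE
P14625	HSP90B1	MRALWVLGLCCVLLTFGSVRA	SP	FALSE	TRUE	9.52	1.446	3	TRUE
Q9Y4L1	HYOU1	MADKVRRQRPRRRVCWALVAVLLADLLALSDT	SP	FALSE	TRUE	3.12	-0.101	3	TRUE
P23284	PPIB	MLRLSERNMKVLLAAALIAGSVFFLLLPGPSAA	SP	FALSE	TRUE	12.1	0.961	3	TRUE
mut-PPIB	mut-PPIB	MLRLGPRNMKVLLPPALIAGSVFFLLLPGPSAA	SP	FALSE	TRUE	24.2	0.814	3	TRUE
Q9Y3A6	TMED5	MGDKIWLPFPVLLLAALPPVLLPGAAG	SP	TRUE	FALSE	29.6	1.074	3	TRUE
mut-TMED5	mut-TMED5	MGDKIWLPFPVLLLAALPPVLLAAAAG	SP	TRUE	FALSE	22.2	1.25	3	TRUE
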