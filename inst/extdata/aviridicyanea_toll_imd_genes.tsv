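gene	family	orf_bp	aa_length	mw_kda	pi	signal_peptide	lrr_spans	tm_span	tir_span	domains	subfamily	accession
Toll-1	Toll	3855	1284	147.03	5.77	1-20	108-131,162-185,186-205,265-288,289-312,314-337,338-360,364-387,388-411,412-435,436-459,460-479,483-506,507-530,531-554,555-574,647-668,671-691,711-769,791-829,872-893,896-917,920-943	1029-1051	1083-1220		P	OQ819300
Toll-2	Toll	3864	1287	146.34	5.69	1-17	86-109,141-164,165-190,193-212,218-241,242-265,266-285,290-315,316-339,340-363,364-387,388-411,412-431,435-461,459-482,483-506,530-552,553-571,581-596,599-618,642-700,722-760,759-778,803-824,827-850,851-870,886-938	956-978	1012-1149		P	OQ819301
Toll-3	Toll	3735	1244	141.20	5.99	1-19	98-121,153-176,177-200,207-230,231-254,255-278,279-302,303-328,329-350,353-376,377-400,401-424,425-447,448-471,472-495,496-519,543-565,612-633,637-659,756-795,796-813,815-837,838-859,862-883,886-914	1009-1031	1063-1197		P	OQ819302
Toll-4	Toll	3972	1323	149.45	5.66	1-15	100-123,154-180,178-201,214-246,238-261,262-285,286-312,313-335,336-359,360-383,384-407,408-431,432-453,455-481,479-502,503-526,597-618,619-640,683-741,763-801,821-843,844-865,868-889,892-915,930-975	1004-1026	1058-1196		P	OQ819303
Toll-5	Toll	3108	1035	119.36	5.84	1-20	186-208,209-232,233-254,257-280,305-328,329-348,353-376,377-400,401-421,452-471,474-497,500-520,546-604,667-688,687-707,725-769	773-795	827-964		sPP	OQ819304
Toll-6	Toll	2571	856	98.26	8.54	1-21	131-155,156-179,184-207,211-233,290-312,313-336,337-360,388-411,412-435,436-458,488-511,512-535	638-660	696-844		sP	OQ819306
Spaetzle-1	signal	612	203	23.62	7.99	1-20				Spaetzle:104-199		OQ834310
Spaetzle-2	signal	561	186	21.09	7.46	1-23				Spaetzle:84-180		OQ834311
Spaetzle-3	signal	975	324	37.82	9.17	1-17				Spaetzle:223-321		OQ834312
Spaetzle-4	signal	579	192	22.30	9.32	1-21				Spaetzle:88-182		OQ834313
Spaetzle-5	signal	624	207	23.98	5.51	1-24				Spaetzle:109-205		OQ834314
Spaetzle-6	signal	597	198	22.88	9.32	1-21				Spaetzle:94-188		OQ834315
Myd88	signal	1236	411	47.17	6.02					DEATH:12-101;TIR:144-279		OQ834300
Pelle	signal	1449	482	55.31	8.53					DEATH:6-89;S_TKc:203-475		OQ834301
Tube	signal	2091	696	77.87	4.86					DEATH:1-116;S_TKc:411-684		OQ834302
Cactus	signal	1125	374	41.90	4.83					ANK:125-154,161-190,194-223,246-275,280-310		OQ834303
Relish-1	signal	2718	905	103.25	5.51					RHD_DNA_bind:80-272;IPT:279-381;ANK:556-588,595-624,628-657,668-703,708-737		OQ834304
Relish-2	signal	2664	887	101.13	5.58					RHD_DNA_bind:62-254;IPT:261-363;ANK:538-570,577-606,610-639,650-685,690-719		OQ834305
Dorsal	signal	2235	744	83.55	8.68					RHD_DNA_bind:62-254;IPT:261-363		OQ834306
Imd	signal	621	207	28.84	6.54					DEATH:111-205		OQ834307
Dredd	signal	1734	577	66.16	6.10					CASc:318-574		OQ834308
TAK1	signal	1386	461	51.55	4.98					PP2Cc:20-364		OQ834309
TAB2-1	signal	1488	495	55.99	8.72					CUE:14-59;ZnF_RBZ:440-464		OQ834316
TAB2-2	signal	1479	492	55.64	8.81					ZnF_RBZ:440-464		OQ834317
TAB2-3	signal	1674	557	62.57	8.77					CUE:14-59;ZnF_RBZ:440-464		OQ834318
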