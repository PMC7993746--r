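symbol	entrez_id	full_name	score_high	score_low	weight
DDAH1	23576	Dimethylarginine dimethylaminohydrolase 1	1	0	3.580
CRABP2	1382	Cellular retinoic acid binding protein 2	0	1	3.009
TGFA	7039	Transforming growth factor alpha	1	0	3.425
SEMA3G	56920	Semaphorin 3G	1	0	3.042
SPATA18	132671	Spermatogenesis associated 18	1	0	4.169
PTTG1	9232	Pituitary tumor-transforming gene 1	0	1	3.344
SCGN	10590	Secretagogin	1	0	4.200
CYP39A1	51302	Cytochrome P450 family 39 subfamily A member 1	1	0	3.595
CLDN4	1364	Claudin 4	1	0	3.541
ZNF395	55893	Zinc finger protein 395	1	0	3.977
IL15RA	3601	Interleukin 15 receptor subunit alpha	0	1	3.859
APLNR	187	Apelin receptor	1	0	3.072
APOLD1	81575	Apolipoprotein L domain containing 1	1	0	3.207
NTN4	59277	Netrin 4	1	0	3.723
PABPC1L	80336	Poly(A) binding protein cytoplasmic 1 like	0	1	3.670
UBE2C	11065	Ubiquitin conjugating enzyme E2 C	0	1	4.217
CDH4	1002	Cadherin 4	1	0	3.183
GNG7	2788	G protein subunit gamma 7	1	0	3.515
CEACAM1	634	CEA cell adhesion molecule 1	1	0	3.506
PLAUR	5329	Plasminogen activator, urokinase receptor	0	1	3.418
SIM2	6493	SIM bHLH transcription factor 2	0	1	3.364
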