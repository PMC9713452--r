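protein	position	ref	alt	phenotype	source	provenance
BMP15	209	C	G	lung squamous cell neoplasms	GDC	results-text
GDF1	227	C	del:145	right atrial isomerism	MalaCards	results-text
GDF6	230	C	R	colon adenocarcinoma	GDC	results-text
GDF6	419	C	Y	colon adenocarcinoma	GDC	results-text
GDF5	438	R	C	colon adenocarcinomas	GDC	results-text
INHBA	244	C	Y	lung adenocarcinomas	GDC	results-text
TGFB1	223	C	R	Camurati-Engelmann disease	GeneCards	results-text
TGFB1	223	C	G	Camurati-Engelmann disease	GeneCards	results-text
TGFB1	223	C	S	Camurati-Engelmann disease	GeneCards	results-text
TGFB1	225	C	R	Camurati-Engelmann disease	GeneCards	results-text
TGFB1	225	C	Y	Camurati-Engelmann disease	GeneCards	results-text
INHBE	29	C	Y	plasma cell tumors	GDC	results-text
INHBB	154	S	C	plasma cell tumors	GDC	results-text
TGFB2	256	C	*	endometrial adenocarcinomas	GDC	results-text
INHA	291	C	W	endometrial adenocarcinoma	GDC	results-text
INHBB	223	R	C	endometrial adenocarcinoma	GDC	results-text
TGFB2	257	C	F	Holt-Oram syndrome	MalaCards	results-text
TGFB2	378	C	Y	Holt-Oram syndrome	MalaCards	results-text
TGFB2	257	C	*	Loeys-Dietz syndrome	MalaCards	results-text
TGFB2	439	C	S	Loeys-Dietz syndrome	MalaCards	results-text
TGFB3	409	C	Y	Loeys-Dietz syndrome	MalaCards	results-text
TGFB2	246	C	Y	lung adenocarcinoma	GDC	results-text
TGFB2	407	C	S	lung adenocarcinoma	GDC	results-text
LTBP1	1022	C	Y	plasma cell tumors	GDC	results-text
FBN1	1431	C	Y	plasma cell tumors	GDC	results-text
FBN1	1687	C	F	plasma cell tumors	GDC	results-text
FBN2	1178	C	Y	plasma cell tumors	GDC	synthetic
FBN2	1378	C	Y	plasma cell tumors	GDC	synthetic
FBN2	1406	C	F	plasma cell tumors	GDC	results-text
FBN2	1579	C	G	plasma cell tumors	GDC	results-text
FBN2	1608	C	Y	plasma cell tumors	GDC	results-text
FBN3	130	C	Y	plasma cell tumors	GDC	synthetic
FBN3	1215	C	Y	plasma cell tumors	GDC	synthetic
FBN3	1519	C	R	plasma cell tumors	GDC	results-text
FBN1	1431	C	W	Loeys-Dietz syndrome	GDC	results-text
LTBP1	559	C	Y	colon adenocarcinoma	GDC	results-text
LTBP1	594	C	W	colon adenocarcinoma	GDC	results-text
FBN1	905	C	Y	colon adenocarcinoma	GDC	synthetic
FBN1	1120	C	R	colon adenocarcinoma	GDC	synthetic
FBN1	1530	C	S	colon adenocarcinoma	GDC	synthetic
FBN2	990	C	Y	colon adenocarcinoma	GDC	synthetic
FBN2	1275	C	R	colon adenocarcinoma	GDC	synthetic
FBN2	1406	C	S	colon adenocarcinoma	GDC	results-text
FBN3	860	C	Y	colon adenocarcinoma	GDC	synthetic
FBN3	1042	C	F	colon adenocarcinoma	GDC	synthetic
FBN3	1330	C	R	colon adenocarcinoma	GDC	synthetic
LTBP2	1320	C	Y	colon adenocarcinoma	GDC	table-transcription
LTBP1	740	C	Y	endometrial adenocarcinoma	GDC	synthetic
LTBP3	715	C	R	endometrial adenocarcinoma	GDC	synthetic
LRC32	342	C	R	endometrial adenocarcinoma	GDC	results-text
SELE	428	C	G	endometrial adenocarcinoma	GDC	synthetic
FBN2	1460	C	Y	endometrial adenocarcinoma	GDC	synthetic
FBN2	1702	C	S	endometrial adenocarcinoma	GDC	synthetic
FBN3	702	C	W	endometrial adenocarcinoma	GDC	synthetic
FBN3	1390	C	Y	endometrial adenocarcinoma	GDC	synthetic
LTBP2	575	C	Y	endometrial adenocarcinoma	GDC	synthetic
LTBP2	840	C	R	endometrial adenocarcinoma	GDC	synthetic
LTBP2	1301	C	S	endometrial adenocarcinoma	GDC	synthetic
LTBP2	1310	C	F	endometrial adenocarcinoma	GDC	synthetic
FBN1	610	C	Y	endometrial adenocarcinoma	GDC	synthetic
FBN1	735	C	G	endometrial adenocarcinoma	GDC	synthetic
FBN1	1224	C	R	endometrial adenocarcinoma	GDC	synthetic
FBN1	1980	C	Y	endometrial adenocarcinoma	GDC	synthetic
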