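partner	kind	ordinal	start	end
LTBP1	TB8CYS	1	540	600
LTBP1	EGF	4	720	760
LTBP1	EGF	7	1000	1040
LTBP1	TB8CYS	3	1340	1400
LTBP2	TB8CYS	1	560	620
LTBP2	EGF	5	820	860
LTBP2	TB8CYS	3	1290	1350
LTBP3	TB8CYS	2	700	760
LTBP4	TB8CYS	3	1200	1260
FBN1	EGF	12	890	930
FBN1	EGF	18	1100	1140
FBN1	EGF	24	1410	1450
FBN1	EGF	25	1515	1550
FBN1	EGF	28	1670	1710
FBN1	TB8CYS	6	1850	1910
FBN2	EGF	9	975	1015
FBN2	EGF	16	1160	1200
FBN2	EGF	19	1260	1300
FBN2	EGF	22	1370	1410
FBN2	EGF	24	1445	1485
FBN2	EGF	30	1690	1730
FBN2	TB8CYS	6	1570	1620
FBN3	EGF	2	115	155
FBN3	EGF	20	1200	1240
FBN3	TB8CYS	6	1500	1550
LRC32	LRR	12	330	355
LRC33	LRR	10	290	315
SELE	SUSHI	3	400	460
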