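protein	region	position	label
BMP10	B8	240	CYS@1
BMP10	B8	243	CYS@4
BMP15	B8	209	CYS@4
BMP2	ASSN	31	CYS@1
BMP2	B8	245	CYS@1
BMP2	B8	247	CYS@3
BMP4	ASSN	32	CYS@1
BMP4	B8	248	CYS@1
BMP4	B8	250	CYS@3
BMP5	B8	252	CYS@1
BMP6	B8	250	CYS@1
BMP7	ASSN	37	CYS@1
BMP7	B8	255	CYS@1
BMP7	B8	257	CYS@3
GDF1	B8	227	CYS@4
GDF11	ASSN	140	CYS@1
GDF11	ASSN	143	CYS@4
GDF2	ASSN	30	CYS@1
GDF2	B8	237	CYS@4
GDF5	ASSN	35	CYS@1
GDF5	B8	240	CYS@1
GDF6	B8	230	CYS@4
GDF7	B8	238	CYS@1
GDF7	B8	240	CYS@3
GDF9	B8	247	CYS@4
GDNF	ASSN	27	CYS@1
GDNF	ASSN	30	CYS@4
INHA	ASSN	28	CYS@1
INHA	B8	232	CYS@1
INHA	B8	235	CYS@4
INHBA	ASSN	35	CYS@1
INHBA	ASSN	38	CYS@4
INHBA	B8	244	CYS@1
INHBA	B8	247	CYS@4
INHBB	ASSN	147	CYS@1
INHBB	ASSN	150	CYS@4
INHBB	B8	226	CYS@1
INHBB	B8	229	CYS@4
INHBC	ASSN	31	CYS@1
INHBC	ASSN	34	CYS@4
INHBC	B8	235	CYS@1
INHBE	ASSN	26	CYS@1
INHBE	ASSN	29	CYS@4
MSTN	ASSN	30	CYS@1
MSTN	ASSN	33	CYS@4
NODAL	ASSN	30	CYS@1
NODAL	B8	240	CYS@1
TGFB1	ASSN	33	CYS@1
TGFB1	B8	223	CYS@1
TGFB1	B8	225	CYS@3
TGFB2	ASSN	24	CYS@1
TGFB2	B8	254	CYS@1
TGFB2	B8	256	CYS@3
TGFB2	B8	257	CYS@4
TGFB3	ASSN	27	CYS@1
TGFB3	B8	261	CYS@1
TGFB3	B8	263	CYS@3
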