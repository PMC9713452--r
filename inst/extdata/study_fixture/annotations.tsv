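id	accession	subfamily	signal_start	signal_end	cleavage_pos
TGFB1	SYNTH:TGFB1	TGF-beta	1	29	232
TGFB2	SYNTH:TGFB2	TGF-beta	1	20	262
TGFB3	SYNTH:TGFB3	TGF-beta	1	23	268
NODAL	SYNTH:NODAL	TGF-beta	1	26	247
AMH	SYNTH:AMH	TGF-beta	1	24	238
LEFTY1	SYNTH:LEFTY1	TGF-beta	1	21	236
LEFTY2	SYNTH:LEFTY2	TGF-beta	1	21	237
GDF15	SYNTH:GDF15	TGF-beta	1	29	243
INHA	SYNTH:INHA	Activin	1	24	240
INHBA	SYNTH:INHBA	Activin	1	28	252
INHBB	SYNTH:INHBB	Activin	1	28	236
INHBC	SYNTH:INHBC	Activin	1	22	243
INHBE	SYNTH:INHBE	Activin	1	25	238
MSTN	SYNTH:MSTN	Activin	1	23	242
GDF11	SYNTH:GDF11	Activin	1	24	258
GDF3	SYNTH:GDF3	Activin	1	25	238
BMP2	SYNTH:BMP2	BMP	1	23	253
BMP4	SYNTH:BMP4	BMP	1	24	256
BMP7	SYNTH:BMP7	BMP	1	29	263
BMP5	SYNTH:BMP5	BMP	1	28	260
BMP6	SYNTH:BMP6	BMP	1	26	258
BMP10	SYNTH:BMP10	BMP	1	21	248
GDF7	SYNTH:GDF7	BMP	1	25	246
GDF9	SYNTH:GDF9	BMP	1	27	252
GDF2	SYNTH:GDF2	BMP	1	22	242
BMP15	SYNTH:BMP15	BMP	1	18	214
GDF1	SYNTH:GDF1	BMP	1	28	235
GDF5	SYNTH:GDF5	BMP	1	27	248
GDF6	SYNTH:GDF6	BMP	1	27	236
BMP3	SYNTH:BMP3	BMP	1	23	246
BMP8A	SYNTH:BMP8A	BMP	1	22	244
BMP8B	SYNTH:BMP8B	BMP	1	22	245
GDF10	SYNTH:GDF10	BMP	1	26	250
GDNF	SYNTH:GDNF	outgroup	1	19	78
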