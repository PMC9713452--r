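cutoff: 0.2
threshold: 0.2
n_family: 33
windows:
  assn:
  - 131
  - 134
  b8:
  - 375
  - 378
synonyms:
  plasma cell tumor: plasma cell tumors
  colon adenocarcinomas: colon adenocarcinoma
  endometrial adenocarcinomas: endometrial adenocarcinoma
  lung adenocarcinomas: lung adenocarcinoma
known_interactions:
- - TGFB1
  - TGFB1
- - INHA
  - INHBB
- - TGFB1
  - LTBP1
- - TGFB1
  - LTBP3
- - TGFB1
  - LTBP4
- - TGFB1
  - LRC32
- - TGFB1
  - LRC33
near_region:
- protein: GDF5
  position: 438
  region: LIGAND
- protein: INHBB
  position: 154
  region: ASSN
- protein: INHBB
  position: 223
  region: B8
partners:
- LTBP1
- LTBP2
- LTBP3
- LTBP4
- FBN1
- FBN2
- FBN3
- LRC32
- LRC33
- SELE
binding_pairs:
  ltbp1_tb3:
  - 1359
  - 1384
  lrc32:
  - 211
  - 350
spacing_tolerance: 5
docking_reference: LTBP1_TB3
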