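# Builds the packaged fixture under inst/extdata/study_fixture/.
#
# The mutation catalog, partner domains, known-interaction set and the
# conserved-cysteine table are transcriptions of the published tables and
# results text (provenance column: results-text / table-transcription).
# The precursor sequences and the prodomain alignment are constructed
# synthetic stand-ins (no accessions were deposited): every published
# precursor coordinate is honoured, all other residues are deterministic
# filler with no cysteines outside the designed columns.
#
# Layout of the stand-in alignment (width 390):
#   columns   1-130  amino-terminal block, right-aligned (leading gaps)
#   columns 131-134  Association (ASSN) region window
#   columns 135-374  middle block, right-aligned
#   columns 375-378  beta-8 (B8) region window
#   columns 379-390  carboxy-terminal tail, left-aligned

out_dir <- file.path("inst", "extdata", "study_fixture")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

PRE_END <- 130L; ASSN <- 131L:134L; MID_END <- 374L; B8 <- 375L:378L
WIDTH <- 390L

# id subfamily signal_end assn_anchor assn_labels b8_anchor b8_labels
# cleavage precursor_length
ptab <- read.table(header = TRUE, text = "
id     subfamily signal_end a   assn   b   b8    k   len
TGFB1  TGF-beta  29  33 1    223 1,3  232 342
TGFB2  TGF-beta  20  24 1    254 1,3,4 262 460
TGFB3  TGF-beta  23  27 1    261 1,3  268 450
NODAL  TGF-beta  26  30 1    240 1    247 357
AMH    TGF-beta  24  33 -    230 -    238 348
LEFTY1 TGF-beta  21  30 -    228 -    236 346
LEFTY2 TGF-beta  21  31 -    229 -    237 347
GDF15  TGF-beta  29  38 -    235 -    243 353
INHA   Activin   24  28 1    232 1,4  240 370
INHBA  Activin   28  35 1,4  244 1,4  252 362
INHBB  Activin   28  147 1,4 226 1,4  236 346
INHBC  Activin   22  31 1,4  235 1    243 353
INHBE  Activin   25  26 1,4  230 -    238 348
MSTN   Activin   23  30 1,4  235 -    242 352
GDF11  Activin   24  140 1,4 250 -    258 368
GDF3   Activin   25  33 -    230 -    238 348
BMP2   BMP       23  31 1    245 1,3  253 363
BMP4   BMP       24  32 1    248 1,3  256 366
BMP7   BMP       29  37 1    255 1,3  263 373
BMP5   BMP       28  36 -    252 1    260 370
BMP6   BMP       26  34 -    250 1    258 368
BMP10  BMP       21  29 -    240 1,4  248 358
GDF7   BMP       25  33 -    238 1,3  246 356
GDF9   BMP       27  35 -    244 4    252 362
GDF2   BMP       22  30 1    234 4    242 352
BMP15  BMP       18  26 -    206 4    214 324
GDF1   BMP       28  36 -    224 4    235 345
GDF5   BMP       27  35 1    240 1    248 500
GDF6   BMP       27  35 -    227 4    236 430
BMP3   BMP       23  32 -    238 -    246 356
BMP8A  BMP       22  31 -    236 -    244 354
BMP8B  BMP       22  30 -    237 -    245 355
GDF10  BMP       26  34 -    242 -    250 360
GDNF   outgroup  19  27 1,4  70  -    78  190
", stringsAsFactors = FALSE)

# residues planted beyond the window cysteines (ligand cysteines carrying
# published mutations; reference residues of gain-of-function records)
extras <- list(
  TGFB2 = c("246" = "C", "378" = "C", "407" = "C", "439" = "C"),
  TGFB3 = c("409" = "C"),
  INHA  = c("291" = "C"),
  GDF6  = c("419" = "C"),
  GDF5  = c("438" = "R"),
  INHBB = c("154" = "S", "223" = "R"))

POOL <- strsplit("AGLSTVNQIRKHMFPWY", "")[[1]]  # no C, no D/E
label_offset <- c("1" = 0L, "3" = 2L, "4" = 3L)

planted_positions <- function(row) {
  pos <- integer()
  if (row$assn != "-") {
    offs <- label_offset[strsplit(row$assn, ",")[[1]]]
    pos <- c(pos, row$a + offs)
  }
  if (row$b8 != "-") {
    offs <- label_offset[strsplit(row$b8, ",")[[1]]]
    pos <- c(pos, row$b + offs)
  }
  unname(pos)
}

residue_at <- function(i, row, pos, planted) {
  ex <- extras[[row$id]]
  key <- as.character(pos)
  if (!is.null(ex) && key %in% names(ex)) return(ex[[key]])
  if (pos %in% planted) return("C")
  POOL[((pos * 7L + i * 3L) %% length(POOL)) + 1L]
}

rows <- character(nrow(ptab))
precs <- character(nrow(ptab))
for (i in seq_len(nrow(ptab))) {
  row <- ptab[i, ]
  planted <- planted_positions(row)
  p0 <- row$signal_end + 1L
  stopifnot(row$a - p0 >= 0L, row$a - p0 <= PRE_END,
            row$b - row$a - 4L >= 0L,
            row$b - row$a - 4L <= MID_END - ASSN[4L],
            row$k - row$b - 3L >= 0L, row$k - row$b - 3L <= WIDTH - B8[4L],
            row$len > row$k)
  chars <- rep("-", WIDTH)
  put <- function(cols, positions) {
    for (j in seq_along(cols))
      chars[cols[j]] <<- residue_at(i, row, positions[j], planted)
  }
  n1 <- row$a - p0
  if (n1 > 0L) put((PRE_END - n1 + 1L):PRE_END, p0:(row$a - 1L))
  put(ASSN, row$a:(row$a + 3L))
  n2 <- row$b - row$a - 4L
  if (n2 > 0L) put((MID_END - n2 + 1L):MID_END, (row$a + 4L):(row$b - 1L))
  put(B8, row$b:(row$b + 3L))
  n3 <- row$k - row$b - 3L
  if (n3 > 0L) put(B8[4L] + seq_len(n3), (row$b + 4L):row$k)
  rows[i] <- paste(chars, collapse = "")
  precs[i] <- paste(vapply(seq_len(row$len), function(p)
    residue_at(i, row, p, planted), ""), collapse = "")
}

write_fasta <- function(ids, seqs, path, wrap = 70L) {
  con <- file(path, "w")
  for (j in seq_along(ids)) {
    writeLines(paste0(">", ids[j]), con)
    s <- seqs[j]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))),
               con)
  }
  close(con)
}

write_fasta(ptab$id, precs, file.path(out_dir, "precursors.fasta"))
write_fasta(sprintf("%s|%d-%d", ptab$id, ptab$signal_end + 1L, ptab$k),
            rows, file.path(out_dir, "prodomain_alignment.fasta"))

anno <- data.frame(id = ptab$id,
                   accession = paste0("SYNTH:", ptab$id),
                   subfamily = ptab$subfamily,
                   signal_start = 1L, signal_end = ptab$signal_end,
                   cleavage_pos = ptab$k)
write.table(anno, file.path(out_dir, "annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# conserved-cysteine table (Table-1 transcription over the stand-in
# coordinates), independent of the detection code path
cons <- do.call(rbind, lapply(seq_len(nrow(ptab)), function(i) {
  row <- ptab[i, ]
  out <- NULL
  for (reg in c("assn", "b8")) {
    if (row[[reg]] == "-") next
    anchor <- if (reg == "assn") row$a else row$b
    labs <- strsplit(row[[reg]], ",")[[1]]
    out <- rbind(out, data.frame(
      protein = row$id, region = if (reg == "assn") "ASSN" else "B8",
      position = anchor + unname(label_offset[labs]),
      label = paste0("CYS@", labs), stringsAsFactors = FALSE))
  }
  out
}))
cons <- cons[order(cons$protein, cons$region, cons$position), ]
write.table(cons, file.path(out_dir, "expected_conserved.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

mut <- read.table(header = TRUE, sep = "\t", text = "
protein\tposition\tref\talt\tphenotype\tsource\tprovenance
BMP15\t209\tC\tG\tlung squamous cell neoplasms\tGDC\tresults-text
GDF1\t227\tC\tdel:145\tright atrial isomerism\tMalaCards\tresults-text
GDF6\t230\tC\tR\tcolon adenocarcinoma\tGDC\tresults-text
GDF6\t419\tC\tY\tcolon adenocarcinoma\tGDC\tresults-text
GDF5\t438\tR\tC\tcolon adenocarcinomas\tGDC\tresults-text
INHBA\t244\tC\tY\tlung adenocarcinomas\tGDC\tresults-text
TGFB1\t223\tC\tR\tCamurati-Engelmann disease\tGeneCards\tresults-text
TGFB1\t223\tC\tG\tCamurati-Engelmann disease\tGeneCards\tresults-text
TGFB1\t223\tC\tS\tCamurati-Engelmann disease\tGeneCards\tresults-text
TGFB1\t225\tC\tR\tCamurati-Engelmann disease\tGeneCards\tresults-text
TGFB1\t225\tC\tY\tCamurati-Engelmann disease\tGeneCards\tresults-text
INHBE\t29\tC\tY\tplasma cell tumors\tGDC\tresults-text
INHBB\t154\tS\tC\tplasma cell tumors\tGDC\tresults-text
TGFB2\t256\tC\t*\tendometrial adenocarcinomas\tGDC\tresults-text
INHA\t291\tC\tW\tendometrial adenocarcinoma\tGDC\tresults-text
INHBB\t223\tR\tC\tendometrial adenocarcinoma\tGDC\tresults-text
TGFB2\t257\tC\tF\tHolt-Oram syndrome\tMalaCards\tresults-text
TGFB2\t378\tC\tY\tHolt-Oram syndrome\tMalaCards\tresults-text
TGFB2\t257\tC\t*\tLoeys-Dietz syndrome\tMalaCards\tresults-text
TGFB2\t439\tC\tS\tLoeys-Dietz syndrome\tMalaCards\tresults-text
TGFB3\t409\tC\tY\tLoeys-Dietz syndrome\tMalaCards\tresults-text
TGFB2\t246\tC\tY\tlung adenocarcinoma\tGDC\tresults-text
TGFB2\t407\tC\tS\tlung adenocarcinoma\tGDC\tresults-text
LTBP1\t1022\tC\tY\tplasma cell tumors\tGDC\tresults-text
FBN1\t1431\tC\tY\tplasma cell tumors\tGDC\tresults-text
FBN1\t1687\tC\tF\tplasma cell tumors\tGDC\tresults-text
FBN2\t1178\tC\tY\tplasma cell tumors\tGDC\tsynthetic
FBN2\t1378\tC\tY\tplasma cell tumors\tGDC\tsynthetic
FBN2\t1406\tC\tF\tplasma cell tumors\tGDC\tresults-text
FBN2\t1579\tC\tG\tplasma cell tumors\tGDC\tresults-text
FBN2\t1608\tC\tY\tplasma cell tumors\tGDC\tresults-text
FBN3\t130\tC\tY\tplasma cell tumors\tGDC\tsynthetic
FBN3\t1215\tC\tY\tplasma cell tumors\tGDC\tsynthetic
FBN3\t1519\tC\tR\tplasma cell tumors\tGDC\tresults-text
FBN1\t1431\tC\tW\tLoeys-Dietz syndrome\tGDC\tresults-text
LTBP1\t559\tC\tY\tcolon adenocarcinoma\tGDC\tresults-text
LTBP1\t594\tC\tW\tcolon adenocarcinoma\tGDC\tresults-text
FBN1\t905\tC\tY\tcolon adenocarcinoma\tGDC\tsynthetic
FBN1\t1120\tC\tR\tcolon adenocarcinoma\tGDC\tsynthetic
FBN1\t1530\tC\tS\tcolon adenocarcinoma\tGDC\tsynthetic
FBN2\t990\tC\tY\tcolon adenocarcinoma\tGDC\tsynthetic
FBN2\t1275\tC\tR\tcolon adenocarcinoma\tGDC\tsynthetic
FBN2\t1406\tC\tS\tcolon adenocarcinoma\tGDC\tresults-text
FBN3\t860\tC\tY\tcolon adenocarcinoma\tGDC\tsynthetic
FBN3\t1042\tC\tF\tcolon adenocarcinoma\tGDC\tsynthetic
FBN3\t1330\tC\tR\tcolon adenocarcinoma\tGDC\tsynthetic
LTBP2\t1320\tC\tY\tcolon adenocarcinoma\tGDC\ttable-transcription
LTBP1\t740\tC\tY\tendometrial adenocarcinoma\tGDC\tsynthetic
LTBP3\t715\tC\tR\tendometrial adenocarcinoma\tGDC\tsynthetic
LRC32\t342\tC\tR\tendometrial adenocarcinoma\tGDC\tresults-text
SELE\t428\tC\tG\tendometrial adenocarcinoma\tGDC\tsynthetic
FBN2\t1460\tC\tY\tendometrial adenocarcinoma\tGDC\tsynthetic
FBN2\t1702\tC\tS\tendometrial adenocarcinoma\tGDC\tsynthetic
FBN3\t702\tC\tW\tendometrial adenocarcinoma\tGDC\tsynthetic
FBN3\t1390\tC\tY\tendometrial adenocarcinoma\tGDC\tsynthetic
LTBP2\t575\tC\tY\tendometrial adenocarcinoma\tGDC\tsynthetic
LTBP2\t840\tC\tR\tendometrial adenocarcinoma\tGDC\tsynthetic
LTBP2\t1301\tC\tS\tendometrial adenocarcinoma\tGDC\tsynthetic
LTBP2\t1310\tC\tF\tendometrial adenocarcinoma\tGDC\tsynthetic
FBN1\t610\tC\tY\tendometrial adenocarcinoma\tGDC\tsynthetic
FBN1\t735\tC\tG\tendometrial adenocarcinoma\tGDC\tsynthetic
FBN1\t1224\tC\tR\tendometrial adenocarcinoma\tGDC\tsynthetic
FBN1\t1980\tC\tY\tendometrial adenocarcinoma\tGDC\tsynthetic
", stringsAsFactors = FALSE, quote = "")
write.table(mut, file.path(out_dir, "mutations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

dom <- read.table(header = TRUE, text = "
partner kind ordinal start end
LTBP1 TB8CYS 1 540 600
LTBP1 EGF 4 720 760
LTBP1 EGF 7 1000 1040
LTBP1 TB8CYS 3 1340 1400
LTBP2 TB8CYS 1 560 620
LTBP2 EGF 5 820 860
LTBP2 TB8CYS 3 1290 1350
LTBP3 TB8CYS 2 700 760
LTBP4 TB8CYS 3 1200 1260
FBN1 EGF 12 890 930
FBN1 EGF 18 1100 1140
FBN1 EGF 24 1410 1450
FBN1 EGF 25 1515 1550
FBN1 EGF 28 1670 1710
FBN1 TB8CYS 6 1850 1910
FBN2 EGF 9 975 1015
FBN2 EGF 16 1160 1200
FBN2 EGF 19 1260 1300
FBN2 EGF 22 1370 1410
FBN2 EGF 24 1445 1485
FBN2 EGF 30 1690 1730
FBN2 TB8CYS 6 1570 1620
FBN3 EGF 2 115 155
FBN3 EGF 20 1200 1240
FBN3 TB8CYS 6 1500 1550
LRC32 LRR 12 330 355
LRC33 LRR 10 290 315
SELE SUSHI 3 400 460
", stringsAsFactors = FALSE)
write.table(dom, file.path(out_dir, "partner_domains.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# docking-site comparison stand-in: LTBP1 TB3 vs FBN1/2/3 TB6
dock <- c(
  LTBP1_TB3 = "ASCTELVNGCSDTACLDVNGSCTALVNCGSCFPTACLVDNGESCTA",
  FBN1_TB6  = "STCASVLDNCGDSTCVSLGENCASTLVCNGC--STCALSVDENCGS",
  FBN2_TB6  = "TSCLTVAEGCNDTSCLTVNDGCSALVTCGNC--TSCLATVEEGCNS",
  FBN3_TB6  = "GNCSALVDTCSEGNCAALVETCGSNLACTVC--GSCNLGADDTCSG")
write_fasta(names(dock), unname(dock),
            file.path(out_dir, "docking_tb_alignment.fasta"))

config <- list(
  cutoff = 0.2,
  threshold = 0.2,
  n_family = 33L,
  windows = list(assn = c(131L, 134L), b8 = c(375L, 378L)),
  synonyms = list(
    "plasma cell tumor" = "plasma cell tumors",
    "colon adenocarcinomas" = "colon adenocarcinoma",
    "endometrial adenocarcinomas" = "endometrial adenocarcinoma",
    "lung adenocarcinomas" = "lung adenocarcinoma"),
  known_interactions = list(
    c("TGFB1", "TGFB1"), c("INHA", "INHBB"), c("TGFB1", "LTBP1"),
    c("TGFB1", "LTBP3"), c("TGFB1", "LTBP4"), c("TGFB1", "LRC32"),
    c("TGFB1", "LRC33")),
  near_region = list(
    list(protein = "GDF5", position = 438L, region = "LIGAND"),
    list(protein = "INHBB", position = 154L, region = "ASSN"),
    list(protein = "INHBB", position = 223L, region = "B8")),
  partners = c("LTBP1", "LTBP2", "LTBP3", "LTBP4", "FBN1", "FBN2",
               "FBN3", "LRC32", "LRC33", "SELE"),
  binding_pairs = list(ltbp1_tb3 = c(1359L, 1384L),
                       lrc32 = c(211L, 350L)),
  spacing_tolerance = 5L,
  docking_reference = "LTBP1_TB3")
yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

files <- sort(setdiff(list.files(out_dir), "MANIFEST"))
md5 <- tools::md5sum(file.path(out_dir, files))
writeLines(sprintf("%s  %s", unname(md5), files),
           file.path(out_dir, "MANIFEST"))
cat("fixture written to", out_dir, "\n")
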