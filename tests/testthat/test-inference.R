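test_that("a shared phenotype across distinct proteins yields all pairs", {
  anno <- famAnno(c("P1", "P2", "P3", "P4"), "BMP")
  catalog <- rbind(
    catRow("P1", 10, "CYS_LOSS", "PRODOMAIN_CONSERVED", "tumor a"),
    catRow("P2", 20, "CYS_LOSS", "PRODOMAIN_CONSERVED", "tumor a"),
    catRow("P3", 30, "CYS_LOSS", "LIGAND", "tumor a"),
    catRow("P4", 40, "CYS_LOSS", "PRODOMAIN_CONSERVED", "tumor b"))
  hyp <- proposeHeterodimers(catalog, anno)
  # 3 qualifying proteins -> C(3,2) = 3 pairs
  expect_identical(nrow(hyp), 3L)
  expect_setequal(canonicalPair(hyp$member1, hyp$member2),
                  c("P1|P2", "P1|P3", "P2|P3"))
  expect_true(all(hyp$novel))
  expect_true(all(hyp$scope == "WITHIN_SUBFAMILY"))
})

test_that("homotypic hypotheses arise only without a heterotypic partner", {
  anno <- famAnno(c("TGFB2", "GDF5", "GDF6"),
                  c("TGF-beta", "BMP", "BMP"))
  # one protein, two distinct qualifying positions -> homotypic dimer
  holt <- rbind(
    catRow("TGFB2", 257, "CYS_LOSS", "PRODOMAIN_CONSERVED",
           "holt-oram syndrome", region = "B8"),
    catRow("TGFB2", 378, "CYS_LOSS", "LIGAND", "holt-oram syndrome"))
  hyp <- proposeHeterodimers(holt, anno)
  expect_identical(nrow(hyp), 1L)
  expect_identical(c(hyp$member1, hyp$member2), c("TGFB2", "TGFB2"))
  expect_identical(hyp$scope, "WITHIN_SUBFAMILY")

  # a second protein with the phenotype: only the heterotypic pair is
  # emitted, the homotypic reading is dropped
  colon <- rbind(
    catRow("GDF6", 230, "CYS_LOSS", "PRODOMAIN_CONSERVED",
           "colon adenocarcinoma", region = "B8"),
    catRow("GDF6", 419, "CYS_LOSS", "LIGAND", "colon adenocarcinoma"),
    catRow("GDF5", 438, "CYS_GAIN", "LIGAND", "colon adenocarcinoma",
           near = TRUE))
  hyp2 <- proposeHeterodimers(colon, anno)
  expect_identical(canonicalPair(hyp2$member1, hyp2$member2), "GDF5|GDF6")

  # a single qualifying position never yields a homotypic pair
  single <- catRow("GDF6", 230, "CYS_LOSS", "PRODOMAIN_CONSERVED",
                   "colon adenocarcinoma")
  expect_identical(nrow(proposeHeterodimers(single, anno)), 0L)
})

test_that("known interactions are emitted but flagged non-novel", {
  anno <- famAnno(c("TGFB2", "INHA", "INHBB"),
                  c("TGF-beta", "Activin", "Activin"))
  catalog <- rbind(
    catRow("TGFB2", 256, "CYS_LOSS", "PRODOMAIN_CONSERVED",
           "endometrial adenocarcinoma", region = "B8"),
    catRow("INHA", 291, "CYS_LOSS", "LIGAND",
           "endometrial adenocarcinoma"),
    catRow("INHBB", 223, "CYS_GAIN", "PRODOMAIN_OTHER",
           "endometrial adenocarcinoma", near = TRUE))
  hyp <- proposeHeterodimers(catalog, anno,
                             known = canonicalPair("INHA", "INHBB"))
  keys <- canonicalPair(hyp$member1, hyp$member2)
  expect_setequal(keys, c("INHA|INHBB", "INHA|TGFB2", "INHBB|TGFB2"))
  expect_identical(hyp$novel[keys == "INHA|INHBB"], FALSE)
  expect_identical(sum(hyp$novel), 2L)
  expect_setequal(hyp$scope[hyp$novel], "ACROSS_SUBFAMILY")
})

test_that("non-qualifying evidence is ignored by the heterodimer rule", {
  anno <- famAnno(c("P1", "P2"), "BMP")
  catalog <- rbind(
    catRow("P1", 10, "CYS_LOSS", "PRODOMAIN_CONSERVED", "t"),
    catRow("P2", 20, "CYS_LOSS", "PRODOMAIN_OTHER", "t"),   # not qualifying
    catRow("P2", 30, "CYS_GAIN", "LIGAND", "t", near = FALSE),
    catRow("P2", 40, "OTHER", "LIGAND", "t"))
  expect_identical(nrow(proposeHeterodimers(catalog, anno)), 0L)
})

test_that("the engine equals a brute-force double loop on random instances", {
  set.seed(101)
  for (k in 1:12) {
    n <- sample(4:20, 1)
    ids <- sprintf("P%02d", seq_len(n))
    anno <- famAnno(ids, sample(c("TGF-beta", "Activin", "BMP"), n,
                                replace = TRUE))
    m <- sample(5:40, 1)
    catalog <- do.call(rbind, lapply(seq_len(m), function(i) {
      catRow(sample(ids, 1), sample(1:300, 1),
             sample(c("CYS_LOSS", "CYS_GAIN", "OTHER"), 1),
             sample(c("PRODOMAIN_CONSERVED", "PRODOMAIN_OTHER",
                      "LIGAND"), 1),
             sample(sprintf("phen%02d", 1:6), 1),
             near = sample(c(TRUE, FALSE), 1),
             id = sprintf("m%03d", i))
    }))
    known <- if (k %% 2 == 0) canonicalPair(ids[1], ids[2]) else character()
    got <- proposeHeterodimers(catalog, anno, known)
    want <- bruteForceHeterodimers(catalog, anno, known)
    expect_identical(got[, c("member1", "member2", "phenotype_key",
                             "novel")], want)
    # row-order invariance
    perm <- sample(nrow(catalog))
    got_p <- proposeHeterodimers(catalog[perm, ], anno, known)
    expect_identical(got_p, got)
  }
})

test_that("partner edges require a conserved-cysteine anchor and a matching partner loss", {
  anno <- famAnno(c("INHBE", "TGFB2"), c("Activin", "TGF-beta"))
  partners <- c("LTBP1", "FBN1", "FBN2", "FBN3", "SELE")
  catalog <- rbind(
    catRow("INHBE", 29, "CYS_LOSS", "PRODOMAIN_CONSERVED",
           "plasma cell tumors", region = "ASSN"),
    catRow("LTBP1", 1022, "CYS_LOSS", "PARTNER_DOMAIN",
           "plasma cell tumors"),
    catRow("FBN1", 1431, "CYS_LOSS", "PARTNER_DOMAIN",
           "plasma cell tumors"),
    catRow("FBN1", 1687, "CYS_LOSS", "PARTNER_DOMAIN",
           "plasma cell tumors"),
    catRow("FBN2", 1406, "CYS_LOSS", "UNMAPPED", "plasma cell tumors"),
    catRow("FBN3", 1519, "CYS_LOSS", "PARTNER_DOMAIN",
           "plasma cell tumors"),
    catRow("SELE", 428, "CYS_GAIN", "UNMAPPED", "plasma cell tumors"),
    catRow("SELE", 430, "CYS_LOSS", "UNMAPPED", "other phenotype"))
  hyp <- proposePartnerInteractions(catalog, anno, partners)
  expect_identical(nrow(hyp), 4L)
  expect_setequal(hyp$member2, c("LTBP1", "FBN1", "FBN2", "FBN3"))
  expect_true(all(hyp$member1 == "INHBE"))
  expect_true(all(hyp$anchor_region == "ASSN"))
  # FBN1 edge carries both supporting partner mutations
  supp <- strsplit(hyp$support[hyp$member2 == "FBN1"], ";")[[1]]
  expect_identical(sum(grepl("^FBN1", supp)), 2L)
  # no phenotype overlap -> no edges
  none <- proposePartnerInteractions(
    catRow("INHBE", 29, "CYS_LOSS", "PRODOMAIN_CONSERVED", "unique"),
    anno, partners)
  expect_identical(nrow(none), 0L)
  # brute-force agreement
  bf <- bruteForcePartnerEdges(catalog, anno, partners)
  expect_identical(hyp[, c("member1", "member2", "phenotype_key")], bf)
})

test_that("removing a phenotype removes exactly its hypotheses", {
  set.seed(77)
  ids <- sprintf("P%02d", 1:8)
  anno <- famAnno(ids, "Activin")
  catalog <- do.call(rbind, lapply(1:30, function(i)
    catRow(sample(ids, 1), sample(1:200, 1), "CYS_LOSS",
           "PRODOMAIN_CONSERVED", sample(c("pa", "pb", "pc"), 1),
           id = sprintf("m%03d", i))))
  all_h <- proposeHeterodimers(catalog, anno)
  reduced <- proposeHeterodimers(catalog[catalog$phenotype_key != "pb", ],
                                 anno)
  expect_identical(reduced, all_h[all_h$phenotype_key != "pb", ]
                   |> (\(d) { rownames(d) <- NULL; d })())
})

test_that("hypothesis summaries count distinct novel pairs by scope", {
  anno <- famAnno(c("A1", "A2", "T1"), c("Activin", "Activin",
                                         "TGF-beta"))
  catalog <- rbind(
    catRow("A1", 10, "CYS_LOSS", "PRODOMAIN_CONSERVED", "p1"),
    catRow("A2", 20, "CYS_LOSS", "PRODOMAIN_CONSERVED", "p1"),
    catRow("A1", 11, "CYS_LOSS", "PRODOMAIN_CONSERVED", "p2"),
    catRow("T1", 30, "CYS_LOSS", "LIGAND", "p2"))
  het <- proposeHeterodimers(catalog, anno)
  s <- summarizeHypotheses(het)
  expect_identical(s$novel_heterodimers, 2L)
  expect_identical(s$within_subfamily, 1L)
  expect_identical(s$across_subfamily, 1L)
  s0 <- summarizeHypotheses(proposeHeterodimers(catalog[0, ], anno))
  expect_identical(s0$novel_heterodimers, 0L)
  expect_identical(s0$novel_partner_edges, 0L)
})
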