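test_that("generation is deterministic under a fixed seed", {
  cfg <- syntheticConfig(subfamily_sizes = c("TGF-beta" = 3L,
                                             "Activin" = 3L, "BMP" = 4L),
                         len_range = c(60L, 80L), seed = 11L,
                         planted_pairs = data.frame(
                           a = 1L, b = 2L, phenotype = "shared tumor"))
  f1 <- generateFamily(cfg)
  f2 <- generateFamily(cfg)
  expect_identical(as.character(precursors(f1$proteins)),
                   as.character(precursors(f2$proteins)))
  expect_identical(as.character(alignedRows(f1$alignment)),
                   as.character(alignedRows(f2$alignment)))
  expect_identical(f1$mutations, f2$mutations)
  expect_identical(f1$truth, f2$truth)
  # written files are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeFamily(f1, d1); writeFamily(f2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("an empty configuration yields empty outputs", {
  cfg <- syntheticConfig(subfamily_sizes = c("TGF-beta" = 0L,
                                             "Activin" = 0L, "BMP" = 0L),
                         len_range = c(60L, 80L))
  fam <- generateFamily(cfg)
  expect_null(fam$proteins)
  expect_identical(nrow(fam$mutations), 0L)
  expect_identical(nrow(fam$truth$conserved), 0L)
})

test_that("the pipeline recovers planted truth exactly at zero noise over many seeds", {
  pairs <- data.frame(a = c(1L, 3L, 5L), b = c(2L, 4L, 6L),
                      phenotype = c("tumor alpha", "tumor beta",
                                    "tumor gamma"))
  for (seed in 1:20) {
    cfg <- syntheticConfig(subfamily_sizes = c("TGF-beta" = 4L,
                                               "Activin" = 4L,
                                               "BMP" = 6L),
                           len_range = c(70L, 90L),
                           planted_pairs = pairs, seed = seed)
    fam <- generateFamily(cfg)
    tab <- assignCysLabels(fam$alignment, fam$windows, cfg$threshold)
    expect_identical(tab, fam$truth$conserved)
    anno <- annotations(fam$proteins)
    catalog <- annotateCatalog(parseMutationTable(fam$mutations)$records,
                               tab, anno)
    hyp <- proposeHeterodimers(catalog, anno)
    expect_identical(hyp[, c("member1", "member2", "phenotype_key")],
                     fam$truth$pairs)
    # precision = recall = 1 against the planted edge set
    expect_true(all(hyp$novel))
  }
})

test_that("singleton-phenotype noise leaves the hypothesis set unchanged", {
  pairs <- data.frame(a = c(1L, 3L), b = c(2L, 4L),
                      phenotype = c("tumor alpha", "tumor beta"))
  base <- syntheticConfig(subfamily_sizes = c("TGF-beta" = 4L,
                                              "Activin" = 4L,
                                              "BMP" = 6L),
                          len_range = c(70L, 90L),
                          planted_pairs = pairs, seed = 5L)
  noisy <- syntheticConfig(subfamily_sizes = c("TGF-beta" = 4L,
                                               "Activin" = 4L,
                                               "BMP" = 6L),
                           len_range = c(70L, 90L),
                           planted_pairs = pairs, n_noise = 15L,
                           seed = 5L)
  run <- function(cfg) {
    fam <- generateFamily(cfg)
    tab <- assignCysLabels(fam$alignment, fam$windows, cfg$threshold)
    anno <- annotations(fam$proteins)
    catalog <- annotateCatalog(parseMutationTable(fam$mutations)$records,
                               tab, anno)
    proposeHeterodimers(catalog, anno)[, c("member1", "member2",
                                           "phenotype_key")]
  }
  expect_identical(run(noisy), run(base))
})

test_that("indel mode still maps planted columns to cysteines in the precursor", {
  cfg <- syntheticConfig(subfamily_sizes = c("TGF-beta" = 3L,
                                             "Activin" = 3L, "BMP" = 4L),
                         len_range = c(60L, 80L), indel = TRUE,
                         seed = 13L)
  fam <- generateFamily(cfg)
  tab <- assignCysLabels(fam$alignment, fam$windows, cfg$threshold)
  expect_identical(tab, fam$truth$conserved)
  prec <- as.character(precursors(fam$proteins))
  for (i in seq_len(nrow(tab))) {
    expect_identical(substr(prec[[tab$protein[i]]], tab$position[i],
                            tab$position[i]), "C")
  }
  # rows really vary in ungapped length
  ng <- prodomainEnd(fam$alignment) - prodomainStart(fam$alignment) + 1L
  expect_gt(length(unique(ng)), 1L)
})

test_that("background cysteines outside windows do not disturb labelling", {
  cfg <- syntheticConfig(subfamily_sizes = c("TGF-beta" = 4L,
                                             "Activin" = 4L, "BMP" = 6L),
                         len_range = c(70L, 90L), bg_cys_rate = 0.05,
                         seed = 23L)
  fam <- generateFamily(cfg)
  tab <- assignCysLabels(fam$alignment, fam$windows, cfg$threshold)
  expect_identical(tab, fam$truth$conserved)
})
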