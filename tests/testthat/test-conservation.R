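test_that("similarity-group shading follows the cutoff and plurality rules", {
  scheme <- defaultSimilarityScheme()
  # unanimous column: everything identity at any cutoff
  expect_identical(unique(shadeCells(rep("C", 10), scheme, 0.2)),
                   "IDENTITY")
  # all gaps: unshaded
  expect_identical(unique(shadeCells(rep("-", 6), scheme, 0.2)),
                   "UNSHADED")
  # hand-enumerated mixed column: 3xD + 2xE (acidic group, freq 0.5)
  # and 5xG (freq 0.5) at cutoff 0.5: D is the acidic plurality so D
  # cells are IDENTITY, E cells SIMILAR; G reaches the cutoff alone.
  col <- c(rep("D", 3), rep("E", 2), rep("G", 5))
  got <- shadeCells(col, scheme, 0.5)
  expect_identical(got, c(rep("IDENTITY", 3), rep("SIMILAR", 2),
                          rep("IDENTITY", 5)))
  # X never matches a group
  expect_identical(shadeCells(c("X", rep("A", 9)), scheme, 0.2)[1],
                   "UNSHADED")
  expect_error(shadeCells(col, scheme, 0), "cutoff")
  expect_error(shadeCells(col, scheme, 1.5), "cutoff")
})

test_that("shading agrees with a per-cell counting oracle on random columns", {
  scheme <- defaultSimilarityScheme()
  lookup <- rep(names(scheme), lengths(scheme))
  names(lookup) <- unlist(scheme)
  oracle <- function(column, cutoff) {
    n <- length(column)
    vapply(seq_len(n), function(i) {
      r <- column[i]
      if (r == "-" || r == "X") return("UNSHADED")
      members <- column[column %in% names(lookup)[lookup == lookup[[r]]]]
      if (length(members) / n < cutoff) return("UNSHADED")
      tb <- sort(table(members), decreasing = TRUE)
      top <- sort(names(tb)[tb == max(tb)])[1]
      if (r == top) "IDENTITY" else "SIMILAR"
    }, "")
  }
  set.seed(42)
  alphabet <- c(unlist(scheme), "-", "X")
  for (k in 1:25) {
    column <- sample(alphabet, sample(3:30, 1), replace = TRUE)
    cutoff <- sample(c(0.2, 0.3, 0.5), 1)
    expect_identical(shadeCells(column, scheme, cutoff),
                     oracle(column, cutoff))
  }
})

test_that("shading is row-order equivariant", {
  set.seed(7)
  aln <- randomAln(8, 30)
  sh <- shadeAlignment(aln)
  perm <- sample(seq_len(8))
  rows <- as.character(alignedRows(aln))[perm]
  aln_p <- makeAln(rows, prodomainStart(aln)[perm])
  sh_p <- shadeAlignment(aln_p)
  expect_identical(unname(sh[perm, ]), unname(sh_p))
})

test_that("conserved-column detection uses a closed threshold with gaps in the denominator", {
  # 33 rows; column 1 has 7 cysteines (7/33 >= 0.2), column 2 has 6
  # (6/33 < 0.2), column 3 is cysteine-free
  rows <- vapply(seq_len(33), function(i)
    paste0(if (i <= 7) "C" else "A", if (i <= 6) "C" else "G", "L"), "")
  names(rows) <- sprintf("P%02d", 1:33)
  aln <- makeAln(rows, stats::setNames(rep(1L, 33), names(rows)))
  win <- regionWindow("B8", 1, 3)
  expect_identical(conservedCysColumns(aln, win, 0.2), 1L)
  expect_identical(conservedCysColumns(aln, win, 6 / 33), c(1L, 2L))
  expect_identical(conservedCysColumns(aln, win, 1), integer(0))
  # unanimous column is detected at any threshold <= 1
  rows2 <- stats::setNames(rep("C", 5), sprintf("Q%d", 1:5))
  aln2 <- makeAln(rows2, stats::setNames(rep(1L, 5), names(rows2)))
  expect_identical(conservedCysColumns(aln2, regionWindow("B8", 1, 1), 1),
                   1L)
})

test_that("conserved columns shrink monotonically as the threshold rises", {
  set.seed(11)
  for (k in 1:10) {
    aln <- randomAln(sample(5:20, 1), 40)
    win <- regionWindow("B8", 5, 35)
    thresholds <- sort(stats::runif(4, 0.05, 0.9))
    sets <- lapply(thresholds, function(t)
      conservedCysColumns(aln, win, t))
    for (i in seq_len(length(sets) - 1))
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("column and residue coordinates round-trip through gaps", {
  aln <- makeAln(c(P1 = "A-C", P2 = "GGT"),
                 start = c(P1 = 30L, P2 = 1L))
  expect_identical(columnToResidue(aln, "P1", 3), 31L)
  expect_true(is.na(columnToResidue(aln, "P1", 2)))
  expect_identical(residueToColumn(aln, "P1", 31), 3L)
  expect_error(columnToResidue(aln, "NOPE", 1), "unknown protein")
  set.seed(3)
  aln2 <- randomAln(6, 25)
  for (id in proteinIds(aln2)) {
    for (col in seq_len(25)) {
      pos <- columnToResidue(aln2, id, col)
      if (!is.na(pos))
        expect_identical(residueToColumn(aln2, id, pos), col)
    }
  }
})

test_that("Cys@ labels are assigned by column offset from the region anchor", {
  # three rows emulating the subfamily exemplars: a protein with the
  # first and third cysteines (interchain pair), one with first and
  # fourth (intrachain pair), one with all three positions
  rows <- c(T1 = "GGCACAAG", T2 = "GGCAACAG", T3 = "GGCACCAG",
            T4 = "GGAAAAAG", T5 = "GGCAAAAG", T6 = "GGCACCAG")
  start <- c(T1 = 221L, T2 = 242L, T3 = 252L, T4 = 10L, T5 = 100L,
             T6 = 60L)
  aln <- makeAln(rows, start)
  tab <- assignCysLabels(aln, list(regionWindow("B8", 3, 6)), 0.2)
  t1 <- tab[tab$protein == "T1", ]
  expect_identical(t1$position, c(223L, 225L))
  expect_identical(t1$label, c("CYS@1", "CYS@3"))
  t2 <- tab[tab$protein == "T2", ]
  expect_identical(t2$position, c(244L, 247L))
  expect_identical(t2$label, c("CYS@1", "CYS@4"))
  t3 <- tab[tab$protein == "T3", ]
  expect_identical(t3$position, c(254L, 256L, 257L))
  expect_identical(t3$label, c("CYS@1", "CYS@3", "CYS@4"))
  expect_false("T4" %in% tab$protein)
  # every reported position maps back to a cysteine in the row
  for (i in seq_len(nrow(tab))) {
    col <- residueToColumn(aln, tab$protein[i], tab$position[i])
    chars <- strsplit(rows[[tab$protein[i]]], "")[[1]]
    expect_identical(chars[col], "C")
  }
  # a window with no conserved column yields an empty table
  empty <- assignCysLabels(aln, list(regionWindow("ASSN", 1, 2)), 0.2)
  expect_identical(nrow(empty), 0L)
})

test_that("conservation summaries count distinct proteins and round percentages", {
  tab <- rbind(
    data.frame(protein = sprintf("B%02d", 1:13), region = "B8",
               position = 1:13, label = "CYS@1"),
    data.frame(protein = sprintf("A%02d", 1:4), region = "B8",
               position = 1:4, label = "CYS@1"),
    data.frame(protein = sprintf("T%02d", 1:4), region = "B8",
               position = 1:4, label = "CYS@1"),
    data.frame(protein = c(sprintf("B%02d", 1:5), sprintf("A%02d", 1:6),
                           sprintf("T%02d", 1:5)),
               region = "ASSN", position = 1:16, label = "CYS@1"))
  subfam <- c(stats::setNames(rep("BMP", 13), sprintf("B%02d", 1:13)),
              stats::setNames(rep("Activin", 6), sprintf("A%02d", 1:6)),
              stats::setNames(rep("TGF-beta", 5), sprintf("T%02d", 1:5)))
  s <- summarizeConservation(tab, subfam, nFamily = 33)
  expect_identical(s$per_region$n_proteins[s$per_region$region == "B8"],
                   21L)
  expect_identical(s$per_region$pct[s$per_region$region == "B8"], 64L)
  expect_identical(s$per_region$n_proteins[s$per_region$region == "ASSN"],
                   16L)
  expect_identical(s$per_region$pct[s$per_region$region == "ASSN"], 48L)
  expect_identical(unname(s$by_subfamily["ASSN", c("BMP", "Activin",
                                                   "TGF-beta")]),
                   c(5L, 6L, 5L))
  # empty table: all zeros
  s0 <- summarizeConservation(tab[0, ], subfam, nFamily = 33)
  expect_identical(s0$overall, 0L)
})

test_that("shaded alignment writers emit deterministic text", {
  set.seed(5)
  aln <- randomAln(4, 12, gap_rate = 0)
  sh <- shadeAlignment(aln)
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeShadedAlignment(aln, sh, f1, "text")
  writeShadedAlignment(aln, sh, f2, "text")
  expect_identical(readLines(f1), readLines(f2))
  fh <- withr::local_tempfile(fileext = ".html")
  writeShadedAlignment(aln, sh, fh, "html")
  expect_true(any(grepl("span", readLines(fh))))
})
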