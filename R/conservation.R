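#' Default biochemical similarity scheme
#'
#' Partition of the 20 standard residues into biochemical similarity
#' groups used for BoxShade-style shading: aromatic (FYW), aliphatic
#' (ILVM), basic (RK), acidic (DE), hydroxyl (ST), amide (NQ) and the
#' singleton groups A, G, P, C, H.  'X' belongs to no group and never
#' matches.
#'
#' @return A named list of character vectors of residues.
#' @export
defaultSimilarityScheme <- function() {
  list(aromatic = c("F", "Y", "W"),
       aliphatic = c("I", "L", "V", "M"),
       basic = c("R", "K"),
       acidic = c("D", "E"),
       hydroxyl = c("S", "T"),
       amide = c("N", "Q"),
       A = "A", G = "G", P = "P", C = "C", H = "H")
}

.checkScheme <- function(scheme) {
  res <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(res))
    stop("similarity groups must be disjoint")
  if (!setequal(res, AA_STANDARD))
    stop("similarity scheme must cover exactly the 20 standard residues")
  invisible(scheme)
}

.groupLookup <- function(scheme) {
  g <- rep(names(scheme), lengths(scheme))
  names(g) <- unlist(scheme, use.names = FALSE)
  g
}

#' BoxShade-style shading of one alignment column
#'
#' Cells whose biochemical similarity group reaches the cutoff fraction
#' of all rows (gaps count in the denominator) are shaded: the plurality
#' residue of the group is shaded `IDENTITY`, the remaining group members
#' `SIMILAR`.  Gap cells and `X` are always `UNSHADED`.  Plurality ties
#' are broken alphabetically for reproducible output.
#'
#' @param column Character vector of single residues or `-` (one cell per
#'   alignment row).
#' @param scheme Similarity scheme as from [defaultSimilarityScheme()].
#' @param cutoff Fraction in (0, 1]; default 0.2.
#' @return Character vector of `IDENTITY`, `SIMILAR`, `UNSHADED` per cell.
#' @export
shadeCells <- function(column, scheme = defaultSimilarityScheme(),
                       cutoff = 0.2) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff > 1)
    stop("cutoff must be a fraction in (0, 1]")
  .checkScheme(scheme)
  n <- length(column)
  out <- rep("UNSHADED", n)
  if (n == 0L) return(out)
  lookup <- .groupLookup(scheme)
  grp <- unname(lookup[column])          # NA for gaps and X
  counts <- table(column[!is.na(grp)])
  for (gname in unique(grp[!is.na(grp)])) {
    members <- !is.na(grp) & grp == gname
    gfreq <- sum(members) / n
    if (gfreq < cutoff) next
    mc <- counts[names(counts) %in% column[members]]
    plurality <- sort(names(mc)[mc == max(mc)])[1L]
    out[members] <- ifelse(column[members] == plurality,
                           "IDENTITY", "SIMILAR")
  }
  out
}

.alnMatrix <- function(aln) {
  rows <- strsplit(as.character(aln@aln), "")
  do.call(rbind, rows)
}

#' Shade a whole alignment
#'
#' @param aln A [ProdomainAlignment-class].
#' @inheritParams shadeCells
#' @return A character matrix (rows = proteins, columns = alignment
#'   columns) of shading classes, with row names set to the protein ids.
#' @export
shadeAlignment <- function(aln, scheme = defaultSimilarityScheme(),
                           cutoff = 0.2) {
  m <- .alnMatrix(aln)
  out <- apply(m, 2L, shadeCells, scheme = scheme, cutoff = cutoff)
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(names(aln@aln), NULL))
  out
}

#' Conserved cysteine columns inside a region window
#'
#' Columns of the window whose cysteine fraction (gaps counting in the
#' denominator, so absent proteins dilute conservation) reaches the
#' threshold, in ascending order.  The comparison is closed (`>=`).
#'
#' @param aln A [ProdomainAlignment-class].
#' @param window A [RegionWindow-class].
#' @param threshold Fraction in (0, 1]; default 0.2.
#' @return Integer vector of alignment column indices.
#' @export
conservedCysColumns <- function(aln, window, threshold = 0.2) {
  stopifnot(is(window, "RegionWindow"))
  w <- Biostrings::width(aln@aln)[1]
  if (window@end > w) stop("window exceeds alignment width")
  m <- .alnMatrix(aln)
  cols <- window@start:window@end
  frac <- colSums(m[, cols, drop = FALSE] == "C") / nrow(m)
  cols[frac >= threshold]
}

#' Map an alignment column to a precursor position
#'
#' @param aln A [ProdomainAlignment-class].
#' @param protein_id Row id.
#' @param column Alignment column (1-based).
#' @return The precursor position of that residue, or `NA_integer_` for a
#'   gap cell.  Round-trips with [residueToColumn()].
#' @export
columnToResidue <- function(aln, protein_id, column) {
  if (!protein_id %in% names(aln@aln))
    stop("unknown protein: ", protein_id)
  row <- strsplit(as.character(aln@aln[[protein_id]]), "")[[1]]
  if (column < 1L || column > length(row)) stop("column out of range")
  if (row[column] == "-") return(NA_integer_)
  aln@start[[protein_id]] + sum(row[seq_len(column)] != "-") - 1L
}

#' Map a precursor position to its alignment column
#'
#' @inheritParams columnToResidue
#' @param position Precursor position of a residue in the row.
#' @return The alignment column holding that residue.
#' @export
residueToColumn <- function(aln, protein_id, position) {
  if (!protein_id %in% names(aln@aln))
    stop("unknown protein: ", protein_id)
  start <- aln@start[[protein_id]]
  if (position < start || position > aln@end[[protein_id]])
    stop("position outside the prodomain span")
  row <- strsplit(as.character(aln@aln[[protein_id]]), "")[[1]]
  which(cumsum(row != "-") == (position - start + 1L) & row != "-")[1L]
}

#' Assign positional Cys@ labels inside region windows
#'
#' The anchor column is the first conserved-cysteine column of the
#' window.  A protein with a cysteine at the anchor is labelled `CYS@1`;
#' at anchor + 2 columns `CYS@3` (the middle, third residue of the
#' 4-residue region); at anchor + 3 columns `CYS@4`.  Offsets are
#' measured in alignment columns, so proteins with local indels still
#' receive comparable labels.  Positions are reported in precursor
#' coordinates.
#'
#' @param aln A [ProdomainAlignment-class].
#' @param windows List of [RegionWindow-class] objects.
#' @param threshold Conservation threshold for anchor detection.
#' @return A conserved-cysteine table: `data.frame` with columns
#'   `protein`, `region`, `position`, `label`.  A window with no
#'   conserved column contributes no rows.
#' @export
assignCysLabels <- function(aln, windows, threshold = 0.2) {
  offsets <- c("CYS@1" = 0L, "CYS@3" = 2L, "CYS@4" = 3L)
  m <- .alnMatrix(aln)
  ids <- names(aln@aln)
  out <- list()
  for (win in windows) {
    cons <- conservedCysColumns(aln, win, threshold)
    if (length(cons) == 0L) next
    anchor <- cons[1L]
    for (lab in names(offsets)) {
      col <- anchor + offsets[[lab]]
      if (col > win@end) next
      hit <- which(m[, col] == "C")
      for (i in hit) {
        pos <- columnToResidue(aln, ids[i], col)
        out[[length(out) + 1L]] <- data.frame(
          protein = ids[i], region = win@name, position = pos,
          label = lab, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein = character(), region = character(),
                      position = integer(), label = character(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$protein, tab$region, tab$position), , drop = FALSE]
  rownames(tab) <- NULL
  if (anyDuplicated(tab[c("protein", "region", "label")]))
    stop("duplicate (protein, region, label) in conserved-cysteine table")
  tab
}

#' Summarise conservation counts
#'
#' Counts distinct proteins with at least one conserved cysteine per
#' region and overall, broken down by subfamily, with percentages of the
#' family size rounded to the nearest integer.  Outgroup rows are
#' excluded from all counts.
#'
#' @param tab Conserved-cysteine table from [assignCysLabels()].
#' @param subfamilies Named character vector mapping protein id to
#'   subfamily.
#' @param nFamily Family size used as the percentage denominator
#'   (default 33 human family members).
#' @return A list with elements `per_region` (data.frame of counts and
#'   percentages per region), `by_subfamily` (region x subfamily count
#'   matrix), `overall` (distinct protein count) and `overall_pct`.
#' @export
summarizeConservation <- function(tab, subfamilies, nFamily = 33L) {
  stopifnot(nFamily > 0L)
  tab$subfamily <- unname(subfamilies[tab$protein])
  tab <- tab[is.na(tab$subfamily) | tab$subfamily != "outgroup", ,
             drop = FALSE]
  regions <- sort(unique(tab$region))
  fams <- setdiff(SUBFAMILIES, "outgroup")
  bysub <- matrix(0L, nrow = length(regions), ncol = length(fams),
                  dimnames = list(regions, fams))
  per <- data.frame(region = regions,
                    n_proteins = integer(length(regions)),
                    pct = integer(length(regions)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    sub <- tab[tab$region == regions[i], , drop = FALSE]
    per$n_proteins[i] <- length(unique(sub$protein))
    per$pct[i] <- as.integer(round(100 * per$n_proteins[i] / nFamily))
    cnt <- tapply(sub$protein, sub$subfamily,
                  function(p) length(unique(p)))
    bysub[i, names(cnt)] <- as.integer(cnt)
  }
  overall <- length(unique(tab$protein))
  list(per_region = per, by_subfamily = bysub, overall = overall,
       overall_pct = as.integer(round(100 * overall / nFamily)))
}

#' Write a conserved-cysteine table as TSV
#'
#' @param tab Table from [assignCysLabels()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeConservedTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a shaded alignment rendering
#'
#' Plain-text renderings mark `IDENTITY` cells in uppercase, `SIMILAR`
#' in lowercase and unshaded cells as dots; HTML renderings use two CSS
#' shading classes in the BoxShade tradition.
#'
#' @param aln A [ProdomainAlignment-class].
#' @param shading Matrix from [shadeAlignment()].
#' @param path Output path.
#' @param format `"text"` or `"html"`.
#' @return Invisibly, `path`.
#' @export
writeShadedAlignment <- function(aln, shading, path,
                                 format = c("text", "html")) {
  format <- match.arg(format)
  m <- .alnMatrix(aln)
  ids <- names(aln@aln)
  if (format == "text") {
    rows <- vapply(seq_len(nrow(m)), function(i) {
      cells <- m[i, ]
      cells[shading[i, ] == "SIMILAR"] <- tolower(cells[shading[i, ] ==
                                                          "SIMILAR"])
      cells[shading[i, ] == "UNSHADED" & cells != "-"] <- "."
      paste0(formatC(ids[i], width = 10, flag = "-"),
             paste(cells, collapse = ""))
    }, "")
    writeLines(rows, path)
  } else {
    css <- paste0("<style>pre{font-family:monospace}",
                  ".id{background:#000;color:#fff}",
                  ".sim{background:#bbb}</style>")
    rows <- vapply(seq_len(nrow(m)), function(i) {
      cells <- vapply(seq_len(ncol(m)), function(j) {
        ch <- m[i, j]
        switch(shading[i, j],
               IDENTITY = sprintf("<span class=\"id\">%s</span>", ch),
               SIMILAR = sprintf("<span class=\"sim\">%s</span>", ch),
               ch)
      }, "")
      paste0(formatC(ids[i], width = 10, flag = "-"),
             paste(cells, collapse = ""))
    }, "")
    writeLines(c("<html><head>", css, "</head><body><pre>", rows,
                 "</pre></body></html>"), path)
  }
  invisible(path)
}
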