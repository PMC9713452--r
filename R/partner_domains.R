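#' Read partner-protein domain annotations
#'
#' TSV with header `partner kind ordinal start end`; `kind` is one of
#' `TB8CYS` (the 8-cysteine TGF-beta-binding domain unique to LTBP and
#' fibrillin proteins), `EGF` (6-cysteine EGF-like repeat), `LRR`
#' (leucine-rich repeat) or `SUSHI`.  Spans are inclusive precursor
#' intervals.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with integer `ordinal`, `start`, `end`.
#' @export
readPartnerDomains <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("partner", "kind", "ordinal", "start", "end")
  if (!all(need %in% names(d)))
    stop("partner domain table must have columns: ",
         paste(need, collapse = " "))
  bad <- !d$kind %in% c("TB8CYS", "EGF", "LRR", "SUSHI")
  if (any(bad))
    stop("unknown domain kind: ", paste(unique(d$kind[bad]), collapse = ", "))
  for (col in c("ordinal", "start", "end")) d[[col]] <- as.integer(d[[col]])
  if (any(d$end < d$start)) stop("domain end < start")
  d
}

#' Residue spacing between two cysteines
#'
#' The absolute difference of precursor positions; this convention
#' reproduces the reference spacings of the field: 25 residues between
#' the two TGFB1-binding cysteines of LTBP1 (Cys1359/Cys1384), 35
#' between LTBP1 Cys559/Cys594 and 139 between LRC32 Cys211/Cys350.
#'
#' @param pos_a,pos_b Precursor positions (vectorised).
#' @return Integer distances.
#' @export
cysSpacing <- function(pos_a, pos_b) {
  abs(as.integer(pos_b) - as.integer(pos_a))
}

#' Cysteine positions inside a domain span
#'
#' @param sequence Amino-acid string in precursor coordinates (position 1
#'   = first character).
#' @param start,end Inclusive domain span.
#' @return Ascending precursor positions of `C` within the span.
#' @export
scanDomainCys <- function(sequence, start, end) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (end > length(chars)) stop("span exceeds sequence length")
  idx <- start:end
  idx[chars[idx] == "C"]
}

#' Compare a candidate cysteine spacing to a reference spacing
#'
#' Two cysteine pairs are called similarly spaced when the absolute
#' difference of their spacings is within the tolerance (default 5
#' residues, chosen so that 27 or 28 versus the LTBP1 reference of 25
#' classify as similar while 35 and 139 do not).
#'
#' @param candidate,reference Length-2 position vectors, or scalars
#'   already holding spacings.
#' @param tolerance Non-negative integer, default 5.
#' @return A list with `similar` (logical) and `delta` (the spacing
#'   difference).
#' @export
spacingSimilarity <- function(candidate, reference, tolerance = 5L) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  sp <- function(x) if (length(x) == 2L) cysSpacing(x[1L], x[2L]) else
    as.integer(x)
  delta <- abs(sp(candidate) - sp(reference))
  list(similar = delta <= tolerance, delta = delta)
}

#' Classify acidic docking-site columns across aligned domains
#'
#' Compares acidic (D/E) residue conservation between a reference row
#' (e.g. LTBP1 TGF-beta-binding domain-3, whose five D/E residues form
#' the TGFB1 docking site) and the remaining rows.  Per column:
#' `CONSERVED_ACIDIC_ALL` when every non-gap cell is D or E;
#' `REFERENCE_ONLY` when the reference cell is D/E but at least one
#' non-reference cell is not; `NONREFERENCE_ONLY` when the reference
#' cell is not D/E but all non-reference cells are; otherwise `NONE`.
#'
#' @param aln Named character vector or [Biostrings::AAStringSet] of
#'   equal-length gapped rows.
#' @param reference Row id of the reference sequence.
#' @return A `data.frame` with columns `column` and `class`, carrying the
#'   reference id as attribute `reference`.
#' @export
dockingSiteCompare <- function(aln, reference) {
  rows <- stats::setNames(as.character(aln), names(aln))
  if (length(rows) < 2L) stop("at least 2 rows are required")
  if (!reference %in% names(rows)) stop("reference row not present")
  if (length(unique(nchar(rows))) != 1L)
    stop("all rows must have equal length")
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  acidic <- m == "D" | m == "E"
  gap <- m == "-"
  ref <- which(rownames(m) == reference)
  cls <- vapply(seq_len(ncol(m)), function(j) {
    nongap <- !gap[, j]
    if (any(nongap) && all(acidic[nongap, j])) return("CONSERVED_ACIDIC_ALL")
    others <- setdiff(seq_len(nrow(m)), ref)
    if (acidic[ref, j] && any(!acidic[others, j])) return("REFERENCE_ONLY")
    if (!acidic[ref, j] && all(acidic[others, j])) return("NONREFERENCE_ONLY")
    "NONE"
  }, "")
  out <- data.frame(column = seq_len(ncol(m)), class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  out
}

#' Columns where only the reference row has residues
#'
#' Descriptive check for the two-residue FP insertion unique to the
#' TGFB1-binding domain of LTBP1: reports alignment columns where the
#' reference carries residues opposite gaps in every other row.
#'
#' @inheritParams dockingSiteCompare
#' @return Integer vector of column indices.
#' @export
referenceInsertionColumns <- function(aln, reference) {
  rows <- stats::setNames(as.character(aln), names(aln))
  if (!reference %in% names(rows)) stop("reference row not present")
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  ref <- which(rownames(m) == reference)
  others <- setdiff(seq_len(nrow(m)), ref)
  which(m[ref, ] != "-" &
          apply(m[others, , drop = FALSE] == "-", 2L, all))
}

#' Write a docking-site comparison as TSV
#'
#' @param cmp Output of [dockingSiteCompare()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeDockingComparison <- function(cmp, path) {
  utils::write.table(cmp, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Render a docking-site comparison as HTML
#'
#' Colour-codes the four column classes over the aligned sequences.
#'
#' @inheritParams dockingSiteCompare
#' @param cmp Output of [dockingSiteCompare()] for the same alignment.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeDockingHtml <- function(aln, cmp, path) {
  rows <- stats::setNames(as.character(aln), names(aln))
  colors <- c(CONSERVED_ACIDIC_ALL = "#7fbf7f", REFERENCE_ONLY = "#b39ddb",
              NONREFERENCE_ONLY = "#90caf9", NONE = "")
  html_rows <- vapply(names(rows), function(id) {
    cells <- strsplit(rows[[id]], "")[[1]]
    spans <- vapply(seq_along(cells), function(j) {
      col <- colors[[cmp$class[j]]]
      if (nzchar(col))
        sprintf("<span style=\"background:%s\">%s</span>", col, cells[j])
      else cells[j]
    }, "")
    paste0(formatC(id, width = 12, flag = "-"),
           paste(spans, collapse = ""))
  }, "")
  writeLines(c("<html><body><pre>", html_rows, "</pre></body></html>"),
             path)
  invisible(path)
}
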