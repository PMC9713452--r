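#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

SUBFAMILIES <- c("TGF-beta", "Activin", "BMP", "outgroup")
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "K", "L",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

.checkResidues <- function(seqs) {
  ok <- grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "X]+$"),
              as.character(seqs))
  if (!all(ok)) {
    return(sprintf("non-standard residues in: %s",
                   paste(names(seqs)[!ok], collapse = ", ")))
  }
  NULL
}

#' Precursor protein set
#'
#' Holds full-length TGF-beta family precursor sequences together with
#' their curated annotations: subfamily membership, signal-peptide span and
#' the position of the last prodomain residue (the prodomain/ligand
#' cleavage site).  All coordinates are 1-based precursor coordinates with
#' Met1 = 1; a missing signal peptide is encoded as `NA` in both signal
#' columns.
#'
#' @slot seqs An [Biostrings::AAStringSet] of precursor sequences, named by
#'   gene symbol.
#' @slot anno A `data.frame` with one row per sequence and columns `id`,
#'   `accession`, `subfamily`, `signal_start`, `signal_end`,
#'   `cleavage_pos`.
#' @export
setClass("ProteinSet",
         representation(seqs = "AAStringSet", anno = "data.frame"))

setValidity("ProteinSet", function(object) {
  a <- object@anno
  need <- c("id", "accession", "subfamily", "signal_start", "signal_end",
            "cleavage_pos")
  if (!all(need %in% names(a)))
    return(paste("annotation must have columns:", paste(need, collapse = " ")))
  if (anyDuplicated(a$id))
    return(sprintf("duplicated protein id: %s",
                   a$id[duplicated(a$id)][1L]))
  if (!identical(names(object@seqs), a$id))
    return("sequence names and annotation ids differ (order-sensitive)")
  if (!all(a$subfamily %in% SUBFAMILIES))
    return(paste("subfamily must be one of:",
                 paste(SUBFAMILIES, collapse = ", ")))
  msg <- .checkResidues(object@seqs)
  if (!is.null(msg)) return(msg)
  len <- Biostrings::width(object@seqs)
  has_sig <- !is.na(a$signal_end)
  if (any(has_sig & (is.na(a$signal_start) | a$signal_start != 1L)))
    return("signal span, when present, must start at residue 1")
  se <- ifelse(has_sig, a$signal_end, 0L)
  if (any(se >= a$cleavage_pos))
    return("signal_end must be < cleavage_pos")
  if (any(a$cleavage_pos >= len))
    return(sprintf("cleavage_pos >= precursor length for: %s",
                   paste(a$id[a$cleavage_pos >= len], collapse = ", ")))
  TRUE
})

#' Prodomain sequence set
#'
#' Ungapped prodomain sequences trimmed of signal peptide and ligand.
#' Each sequence keeps precursor numbering through the `start`/`end`
#' slots: residue `i` of sequence `p` is precursor position
#' `start[p] + i - 1`, so positions quoted downstream (e.g. TGFB1 Cys33)
#' are precursor coordinates.
#'
#' @slot seqs An [Biostrings::AAStringSet] of prodomain sequences.
#' @slot start Named integer, first precursor position of each prodomain
#'   (signal end + 1, or 1 with no signal).
#' @slot end Named integer, last prodomain residue (cleavage position).
#' @export
setClass("ProdomainSet",
         representation(seqs = "AAStringSet", start = "integer",
                        end = "integer"))

setValidity("ProdomainSet", function(object) {
  ids <- names(object@seqs)
  if (!identical(ids, names(object@start)) ||
      !identical(ids, names(object@end)))
    return("start/end must be named consistently with the sequences")
  if (any(object@end - object@start + 1L != Biostrings::width(object@seqs)))
    return("prodomain width must equal end - start + 1")
  TRUE
})

#' Gapped prodomain alignment
#'
#' A multiple alignment of trimmed prodomains (gap character `-`) that
#' retains, per row, the precursor position of the first residue so that
#' alignment columns map back to precursor coordinates.
#'
#' @slot aln An [Biostrings::AAStringSet] of equal-width gapped rows.
#' @slot start Named integer, precursor position of each row's first
#'   (ungapped) residue.
#' @slot end Named integer, precursor position of each row's last residue.
#' @export
setClass("ProdomainAlignment",
         representation(aln = "AAStringSet", start = "integer",
                        end = "integer"))

setValidity("ProdomainAlignment", function(object) {
  w <- Biostrings::width(object@aln)
  if (length(w) && length(unique(w)) != 1L)
    return("all alignment rows must have equal width")
  ids <- names(object@aln)
  if (is.null(ids) || anyDuplicated(ids))
    return("alignment rows must carry unique names")
  if (!identical(ids, names(object@start)) ||
      !identical(ids, names(object@end)))
    return("start/end must be named consistently with the rows")
  ng <- vapply(strsplit(as.character(object@aln), ""),
               function(x) sum(x != "-"), integer(1))
  if (any(ng != object@end - object@start + 1L))
    return("ungapped row length must equal end - start + 1")
  TRUE
})

#' Region window on an alignment
#'
#' An inclusive 1-based alignment-column interval naming one of the two
#' structurally defined prodomain regions: the Association (`ASSN`) region
#' near the amino terminus (partner binding) or the beta-8 (`B8`) region
#' near the cleavage site (dimerisation).
#'
#' @param name `"ASSN"` or `"B8"`.
#' @param start,end First and last alignment column of the window.
#' @return A `RegionWindow` object.
#' @export
regionWindow <- function(name, start, end) {
  new("RegionWindow", name = name, start = as.integer(start),
      end = as.integer(end))
}

#' @rdname regionWindow
#' @export
setClass("RegionWindow",
         representation(name = "character", start = "integer",
                        end = "integer"))

setValidity("RegionWindow", function(object) {
  if (!object@name %in% c("ASSN", "B8"))
    return("window name must be ASSN or B8")
  if (object@start < 1L || object@end < object@start)
    return("invalid column span")
  TRUE
})

setMethod("show", "ProteinSet", function(object) {
  cat("ProteinSet of", length(object@seqs), "precursors\n")
  tb <- table(object@anno$subfamily)
  cat(" ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
})

setMethod("show", "ProdomainSet", function(object) {
  cat("ProdomainSet of", length(object@seqs), "prodomains",
      sprintf("(lengths %d-%d)\n",
              min(Biostrings::width(object@seqs)),
              max(Biostrings::width(object@seqs))))
})

setMethod("show", "ProdomainAlignment", function(object) {
  cat("ProdomainAlignment:", length(object@aln), "rows x",
      if (length(object@aln)) Biostrings::width(object@aln)[1] else 0L,
      "columns\n")
})

setMethod("show", "RegionWindow", function(object) {
  cat(sprintf("RegionWindow %s: columns %d-%d\n", object@name,
              object@start, object@end))
})

#' Accessors for sequence containers
#'
#' @param x A `ProteinSet`, `ProdomainSet` or `ProdomainAlignment`.
#' @return `proteinIds` returns the character vector of protein ids;
#'   `annotations` the annotation `data.frame`; `precursors` the
#'   `AAStringSet`; `prodomainStart`/`prodomainEnd` named integer vectors
#'   of precursor coordinates; `alignedRows` the gapped `AAStringSet`.
#' @export
proteinIds <- function(x) {
  if (is(x, "ProteinSet")) return(x@anno$id)
  if (is(x, "ProdomainSet") || is(x, "ProdomainAlignment"))
    return(names(if (is(x, "ProdomainSet")) x@seqs else x@aln))
  stop("unsupported object")
}

#' @rdname proteinIds
#' @export
annotations <- function(x) {
  stopifnot(is(x, "ProteinSet"))
  x@anno
}

#' @rdname proteinIds
#' @export
precursors <- function(x) {
  stopifnot(is(x, "ProteinSet"))
  x@seqs
}

#' @rdname proteinIds
#' @export
prodomainStart <- function(x) {
  stopifnot(is(x, "ProdomainSet") || is(x, "ProdomainAlignment"))
  x@start
}

#' @rdname proteinIds
#' @export
prodomainEnd <- function(x) {
  stopifnot(is(x, "ProdomainSet") || is(x, "ProdomainAlignment"))
  x@end
}

#' @rdname proteinIds
#' @export
alignedRows <- function(x) {
  stopifnot(is(x, "ProdomainAlignment"))
  x@aln
}
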