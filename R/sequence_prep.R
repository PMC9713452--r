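#' Read precursor sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' conventions used throughout the package: headers are truncated at the
#' first whitespace, sequences are uppercased, an empty file is an error
#' and duplicated ids are an error (naming the offending id).
#'
#' @param path Path to a FASTA file (single-line or wrapped sequences).
#' @return A named [Biostrings::AAStringSet] in file order.
#' @export
readFastaProteins <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  seqs
}

#' Read a precursor annotation table
#'
#' The table is a TSV with header
#' `id accession subfamily signal_start signal_end cleavage_pos`.
#' Empty signal fields mean "no signal peptide".
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with integer coordinate columns.
#' @export
readAnnotationTable <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("id", "accession", "subfamily", "signal_start", "signal_end",
            "cleavage_pos")
  if (!all(need %in% names(a)))
    stop("annotation table must have columns: ",
         paste(need, collapse = " "))
  for (col in c("signal_start", "signal_end", "cleavage_pos"))
    a[[col]] <- as.integer(a[[col]])
  a
}

#' Combine sequences and annotations into a ProteinSet
#'
#' Every sequence id must appear exactly once in the annotation table;
#' the type invariants (signal span starting at 1, signal end <
#' cleavage position < precursor length, standard residues only) are
#' checked by the class validity method.
#'
#' @param seqs A named [Biostrings::AAStringSet] of precursors.
#' @param anno Annotation `data.frame` as from [readAnnotationTable()].
#' @return A [ProteinSet-class] object.
#' @export
applyAnnotations <- function(seqs, anno) {
  ids <- names(seqs)
  missing <- setdiff(ids, anno$id)
  if (length(missing))
    stop("missing annotation row for: ", paste(missing, collapse = ", "))
  dup <- anno$id[duplicated(anno$id)]
  if (length(dup))
    stop("duplicated annotation row for: ", dup[1L])
  anno <- anno[match(ids, anno$id), , drop = FALSE]
  rownames(anno) <- NULL
  new("ProteinSet", seqs = seqs, anno = anno)
}

#' Extract prodomains with precursor numbering
#'
#' Trims the signal peptide (if any) and the ligand from each precursor,
#' keeping residues from signal end + 1 through the cleavage position.
#' Precursor numbering is preserved so that downstream reports agree with
#' coordinates such as TGFB1 Cys33 or Cys223.
#'
#' @param pset A [ProteinSet-class].
#' @return A [ProdomainSet-class].
#' @export
extractProdomains <- function(pset) {
  stopifnot(is(pset, "ProteinSet"))
  validObject(pset)
  a <- pset@anno
  start <- ifelse(is.na(a$signal_end), 1L, a$signal_end + 1L)
  end <- a$cleavage_pos
  seqs <- Biostrings::AAStringSet(substr(as.character(pset@seqs),
                                         start, end))
  names(seqs) <- a$id
  start <- stats::setNames(as.integer(start), a$id)
  end <- stats::setNames(as.integer(end), a$id)
  new("ProdomainSet", seqs = seqs, start = start, end = end)
}

#' Write prodomains as FASTA with coordinate suffixes
#'
#' Headers take the form `id|start-end` in precursor coordinates.
#'
#' @param pdoms A [ProdomainSet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProdomainFasta <- function(pdoms, path) {
  stopifnot(is(pdoms, "ProdomainSet"))
  out <- pdoms@seqs
  names(out) <- sprintf("%s|%d-%d", names(out), pdoms@start, pdoms@end)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Assemble a prodomain alignment object
#'
#' @param gapped A named [Biostrings::AAStringSet] (or named character
#'   vector) of equal-width gapped rows.
#' @param pdoms Optional [ProdomainSet-class]; when supplied, each row's
#'   ungapped content is checked against the corresponding prodomain and
#'   the precursor offsets are taken from it.
#' @param start,end Named integer precursor coordinates, required when
#'   `pdoms` is not given.
#' @return A [ProdomainAlignment-class].
#' @export
makeAlignment <- function(gapped, pdoms = NULL, start = NULL, end = NULL) {
  if (is.character(gapped)) gapped <- Biostrings::AAStringSet(gapped)
  ids <- names(gapped)
  if (!is.null(pdoms)) {
    stopifnot(is(pdoms, "ProdomainSet"))
    if (!all(ids %in% names(pdoms@seqs)))
      stop("alignment rows missing from the prodomain set: ",
           paste(setdiff(ids, names(pdoms@seqs)), collapse = ", "))
    ung <- gsub("-", "", as.character(gapped), fixed = TRUE)
    ref <- as.character(pdoms@seqs)[ids]
    if (!identical(unname(ung), unname(ref)))
      stop("ungapped alignment rows do not match the prodomain sequences")
    start <- pdoms@start[ids]
    end <- pdoms@end[ids]
  }
  new("ProdomainAlignment", aln = gapped, start = start[ids], end = end[ids])
}

#' Read an aligned FASTA or Clustal prodomain alignment
#'
#' Aligned FASTA headers may carry the `id|start-end` coordinate suffix
#' written by [writeProdomainFasta()]; otherwise precursor offsets must be
#' supplied.  Clustal files (`.aln`, header line starting with CLUSTAL)
#' are parsed by block.
#'
#' @param path Alignment file.
#' @param start,end Optional named precursor coordinates overriding any
#'   header suffix.
#' @return A [ProdomainAlignment-class].
#' @export
readProdomainAlignment <- function(path, start = NULL, end = NULL) {
  lines <- readLines(path)
  if (length(lines) && grepl("^CLUSTAL", lines[1])) {
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    body <- body[!grepl("^\\s", body)]  # drop conservation lines
    parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)", body))
    ids <- vapply(parts, `[`, "", 2L)
    seqs <- vapply(parts, `[`, "", 3L)
    rows <- vapply(split(seqs, factor(ids, levels = unique(ids))),
                   paste0, "", collapse = "")
    gapped <- Biostrings::AAStringSet(rows)
  } else {
    gapped <- Biostrings::readAAStringSet(path)
  }
  ids <- names(gapped)
  suf <- regmatches(ids, regexec("^(\\S+?)\\|(\\d+)-(\\d+)$", ids))
  has_suf <- lengths(suf) == 4L
  if (is.null(start) && all(has_suf)) {
    start <- as.integer(vapply(suf, `[`, "", 3L))
    end <- as.integer(vapply(suf, `[`, "", 4L))
    ids <- vapply(suf, `[`, "", 2L)
    names(start) <- ids
    names(end) <- ids
  } else if (is.null(start)) {
    stop("alignment headers carry no coordinates; supply start/end")
  }
  names(gapped) <- ids
  makeAlignment(gapped, start = start[ids], end = end[ids])
}
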