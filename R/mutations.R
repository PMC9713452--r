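#' Parse a tabular mutation catalog
#'
#' Input is a TSV with header
#' `protein position ref alt phenotype source` (extra columns such as a
#' provenance tag are carried through).  `alt` accepts a one-letter
#' residue, `*` for a stop, or `del:<n>` for an in-frame deletion of `n`
#' residues starting at the position.  Malformed rows do not abort the
#' parse: they are collected into an error report and the valid rows are
#' returned.
#'
#' @param path Path to the TSV file, or a `data.frame` with the same
#'   columns.
#' @return A list with `records` (the parsed catalog, one row per valid
#'   input row, with columns `id`, `protein`, `position`, `ref`,
#'   `alt_type` in `AA`/`STOP`/`DEL`, `alt`, `del_length`,
#'   `phenotype_raw`, `source`, plus any extra input columns) and
#'   `errors` (`data.frame` of row number and message).
#' @export
parseMutationTable <- function(path) {
  raw <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""),
                      colClasses = "character")
  }
  if (nrow(raw) == 0L) stop("empty mutation table")
  need <- c("protein", "position", "ref", "alt", "phenotype", "source")
  if (!all(need %in% names(raw)))
    stop("mutation table must have columns: ", paste(need, collapse = " "))
  errors <- list()
  rows <- list()
  extra <- setdiff(names(raw), need)
  for (i in seq_len(nrow(raw))) {
    pos <- suppressWarnings(as.integer(raw$position[i]))
    ref <- toupper(trimws(as.character(raw$ref[i])))
    alt_raw <- trimws(as.character(raw$alt[i]))
    msg <- NULL
    if (is.na(pos) || pos < 1L) msg <- "unparseable position"
    else if (is.na(ref) || !ref %in% AA_STANDARD)
      msg <- "unparseable reference residue"
    alt_type <- alt <- NA_character_
    del_length <- NA_integer_
    if (is.null(msg)) {
      if (is.na(alt_raw) || !nzchar(alt_raw)) {
        msg <- "missing alternate allele"
      } else if (alt_raw == "*") {
        alt_type <- "STOP"
      } else if (grepl("^del:\\d+$", alt_raw, ignore.case = TRUE)) {
        alt_type <- "DEL"
        del_length <- as.integer(sub("^del:", "", tolower(alt_raw)))
      } else if (toupper(alt_raw) %in% AA_STANDARD) {
        alt_type <- "AA"
        alt <- toupper(alt_raw)
      } else {
        msg <- paste0("unparseable alternate allele '", alt_raw, "'")
      }
    }
    if (!is.null(msg)) {
      errors[[length(errors) + 1L]] <-
        data.frame(row = i, message = msg, stringsAsFactors = FALSE)
      next
    }
    rec <- data.frame(
      id = sprintf("%s_%s_%d", raw$protein[i], raw$position[i], i),
      protein = raw$protein[i], position = pos, ref = ref,
      alt_type = alt_type, alt = alt, del_length = del_length,
      phenotype_raw = as.character(raw$phenotype[i]),
      source = as.character(raw$source[i]), stringsAsFactors = FALSE)
    for (col in extra) rec[[col]] <- raw[[col]][i]
    rows[[length(rows) + 1L]] <- rec
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), protein = character(),
               position = integer(), ref = character(),
               alt_type = character(), alt = character(),
               del_length = integer(), phenotype_raw = character(),
               source = character(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(), message = character(),
               stringsAsFactors = FALSE)
  list(records = records, errors = errors)
}

#' Classify the cysteine effect of mutation records
#'
#' A record is `CYS_LOSS` when the reference residue is cysteine and the
#' alternate is anything else -- another residue, a stop, or an in-frame
#' deletion starting at the cysteine.  It is `CYS_GAIN` when a
#' non-cysteine reference is substituted by cysteine.  Everything else is
#' `OTHER`.
#'
#' @param records Catalog `data.frame` from [parseMutationTable()].
#' @return The catalog with an `effect` column added.
#' @export
classifyEffect <- function(records) {
  to_cys <- records$alt_type == "AA" & records$alt == "C"
  records$effect <- ifelse(
    records$ref == "C" & !to_cys, "CYS_LOSS",
    ifelse(records$ref != "C" & to_cys, "CYS_GAIN", "OTHER"))
  records
}

#' Normalise a phenotype string into a matching key
#'
#' Lowercases, trims and collapses internal whitespace; an optional
#' synonym map (named character vector, applied after normalisation) can
#' merge spelling variants such as trailing plurals.  Matching elsewhere
#' in the package is exact on these keys: the databases distinguish
#' tumour cell types (squamous vs adenocarcinoma), so fuzzy matching is
#' deliberately avoided.
#'
#' @param raw Character vector of free-text phenotypes.
#' @param synonyms Optional named character vector `c(variant = key)`.
#' @return Character vector of keys; blank or missing input gives `NA`.
#' @export
normalizePhenotype <- function(raw, synonyms = NULL) {
  key <- tolower(trimws(as.character(raw)))
  key <- gsub("\\s+", " ", key)
  key[!nzchar(key) | is.na(key)] <- NA_character_
  if (length(synonyms)) {
    hit <- !is.na(key) & key %in% names(synonyms)
    key[hit] <- unname(synonyms[key[hit]])
  }
  key
}

#' Annotate mutation records with their feature context
#'
#' For family proteins, a (protein, position) match against the
#' conserved-cysteine table gives `PRODOMAIN_CONSERVED` (with region and
#' label); otherwise positions up to the cleavage site are
#' `PRODOMAIN_OTHER` and positions beyond it are `LIGAND`.  For partner
#' proteins, positions inside an annotated domain are `PARTNER_DOMAIN`
#' (with kind and ordinal), otherwise `UNMAPPED`.  Unknown proteins are
#' `UNMAPPED` with a warning.
#'
#' @param records Catalog with `effect` (see [classifyEffect()]).
#' @param conserved Conserved-cysteine table from [assignCysLabels()].
#' @param anno Family annotation `data.frame` (from a [ProteinSet-class]).
#' @param partnerDomains Partner domain table with columns
#'   `partner kind ordinal start end` (may be empty).
#' @param partnerIds Character vector of partner protein ids (defaults to
#'   those present in `partnerDomains`).
#' @param nearRegion Optional `data.frame` with columns
#'   `protein position region` flagging curated mutations topologically
#'   near a region (a structural judgment, supplied as configuration).
#' @return The catalog with `context`, `region`, `label`, `domain_kind`,
#'   `domain_ordinal` and logical `near_region` columns added.
#' @export
annotateContext <- function(records, conserved, anno,
                            partnerDomains = NULL, partnerIds = NULL,
                            nearRegion = NULL) {
  if (is.null(partnerDomains))
    partnerDomains <- data.frame(partner = character(), kind = character(),
                                 ordinal = integer(), start = integer(),
                                 end = integer(), stringsAsFactors = FALSE)
  if (is.null(partnerIds)) partnerIds <- unique(partnerDomains$partner)
  n <- nrow(records)
  records$context <- rep("UNMAPPED", n)
  records$region <- NA_character_
  records$label <- NA_character_
  records$domain_kind <- NA_character_
  records$domain_ordinal <- NA_integer_
  cleavage <- stats::setNames(anno$cleavage_pos, anno$id)
  unknown <- character()
  for (i in seq_len(n)) {
    p <- records$protein[i]
    pos <- records$position[i]
    if (p %in% anno$id) {
      hit <- conserved$protein == p & conserved$position == pos
      if (any(hit)) {
        records$context[i] <- "PRODOMAIN_CONSERVED"
        records$region[i] <- conserved$region[hit][1L]
        records$label[i] <- conserved$label[hit][1L]
      } else if (pos <= cleavage[[p]]) {
        records$context[i] <- "PRODOMAIN_OTHER"
      } else {
        records$context[i] <- "LIGAND"
      }
    } else if (p %in% partnerIds) {
      d <- partnerDomains[partnerDomains$partner == p &
                            partnerDomains$start <= pos &
                            partnerDomains$end >= pos, , drop = FALSE]
      if (nrow(d)) {
        records$context[i] <- "PARTNER_DOMAIN"
        records$domain_kind[i] <- d$kind[1L]
        records$domain_ordinal[i] <- as.integer(d$ordinal[1L])
      }  # else stays UNMAPPED
    } else {
      unknown <- c(unknown, p)
    }
  }
  if (length(unknown))
    warning("unknown protein(s), left UNMAPPED: ",
            paste(unique(unknown), collapse = ", "))
  records$near_region <- FALSE
  if (!is.null(nearRegion) && nrow(nearRegion)) {
    key <- paste(records$protein, records$position)
    records$near_region <- key %in%
      paste(nearRegion$protein, nearRegion$position)
  }
  records
}

#' Build a fully annotated mutation catalog
#'
#' Convenience wrapper chaining [classifyEffect()],
#' [normalizePhenotype()] and [annotateContext()].
#'
#' @inheritParams annotateContext
#' @param synonyms Optional phenotype synonym map.
#' @return The annotated catalog `data.frame`.
#' @export
annotateCatalog <- function(records, conserved, anno,
                            partnerDomains = NULL, partnerIds = NULL,
                            nearRegion = NULL, synonyms = NULL) {
  records <- classifyEffect(records)
  records$phenotype_key <- normalizePhenotype(records$phenotype_raw,
                                              synonyms)
  annotateContext(records, conserved, anno, partnerDomains, partnerIds,
                  nearRegion)
}

#' Write an annotated catalog as TSV
#'
#' @param records Annotated catalog.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCatalog <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
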