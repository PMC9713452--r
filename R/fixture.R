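#' Load the packaged study fixture
#'
#' Loads the fixture shipped under `extdata/study_fixture`: a
#' transcription of the published conserved-cysteine census, mutation
#' records, partner-domain annotations and analysis configuration for
#' the 33 human TGF-beta family members (plus the GDNF outgroup
#' comparator), together with constructed stand-in precursor sequences
#' and a prodomain alignment that honour every published precursor
#' coordinate (the originals deposit no accessions).  File checksums are
#' verified against the shipped MANIFEST.
#'
#' @param dir Fixture directory; defaults to the installed copy.
#' @return A list with elements `proteins` ([ProteinSet-class]),
#'   `prodomains` ([ProdomainSet-class]), `alignment`
#'   ([ProdomainAlignment-class]), `windows` (list of
#'   [RegionWindow-class]), `conserved` (transcribed conserved-cysteine
#'   table), `mutations` (raw mutation table `data.frame`),
#'   `partner_domains`, `docking` (named character alignment rows) and
#'   `config` (list from YAML).
#' @export
loadStudyFixture <- function(dir = system.file("extdata", "study_fixture",
                                               package = "prodomainCys")) {
  if (!nzchar(dir) || !dir.exists(dir)) stop("fixture directory not found")
  manifest <- readLines(file.path(dir, "MANIFEST"))
  parts <- strsplit(manifest, "  ", fixed = TRUE)
  expected <- stats::setNames(vapply(parts, `[`, "", 1L),
                              vapply(parts, `[`, "", 2L))
  actual <- tools::md5sum(file.path(dir, names(expected)))
  names(actual) <- names(expected)
  bad <- names(expected)[is.na(actual) | actual != expected]
  if (length(bad))
    stop("fixture checksum mismatch: ", paste(bad, collapse = ", "))

  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  seqs <- readFastaProteins(file.path(dir, "precursors.fasta"))
  anno <- readAnnotationTable(file.path(dir, "annotations.tsv"))
  proteins <- applyAnnotations(seqs, anno)
  prodomains <- extractProdomains(proteins)
  alignment <- readProdomainAlignment(
    file.path(dir, "prodomain_alignment.fasta"))
  # cross-check rows against the trimmed prodomains
  alignment <- makeAlignment(alignedRows(alignment), pdoms = prodomains)
  windows <- list(
    regionWindow("ASSN", config$windows$assn[1], config$windows$assn[2]),
    regionWindow("B8", config$windows$b8[1], config$windows$b8[2]))
  conserved <- utils::read.delim(file.path(dir, "expected_conserved.tsv"),
                                 stringsAsFactors = FALSE)
  mutations <- utils::read.delim(file.path(dir, "mutations.tsv"),
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
  partner_domains <- readPartnerDomains(file.path(dir,
                                                  "partner_domains.tsv"))
  dock <- readFastaProteins(file.path(dir, "docking_tb_alignment.fasta"))
  docking <- stats::setNames(as.character(dock), names(dock))

  list(proteins = proteins, prodomains = prodomains,
       alignment = alignment, windows = windows, conserved = conserved,
       mutations = mutations, partner_domains = partner_domains,
       docking = docking, config = config)
}

#' Helpers derived from a fixture configuration
#'
#' `fixtureKnownPairs` canonicalises the configured known-interaction
#' set; `fixtureNearRegion` returns the curated near-region flags;
#' `fixtureSynonyms` the phenotype synonym map as a named vector.
#'
#' @param config The `config` element of [loadStudyFixture()].
#' @return See description.
#' @export
fixtureKnownPairs <- function(config) {
  vapply(config$known_interactions,
         function(p) canonicalPair(p[[1]], p[[2]]), "")
}

#' @rdname fixtureKnownPairs
#' @export
fixtureNearRegion <- function(config) {
  do.call(rbind, lapply(config$near_region, function(x)
    data.frame(protein = x$protein, position = as.integer(x$position),
               region = x$region, stringsAsFactors = FALSE)))
}

#' @rdname fixtureKnownPairs
#' @export
fixtureSynonyms <- function(config) {
  unlist(config$synonyms)
}
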