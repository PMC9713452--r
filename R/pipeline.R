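#' Run the conservation stage
#'
#' Detects conserved cysteine columns in the region windows, assigns
#' Cys@ labels, writes the conserved-cysteine TSV and a shaded
#' alignment rendering, and returns the table with its summary.
#'
#' @param fixture A fixture list as from [loadStudyFixture()] (or any
#'   list with `alignment`, `windows`, `proteins`, `config`).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   file output.
#' @return A list with `conserved` (table) and `summary`.
#' @export
runConservation <- function(fixture, out_dir = NULL) {
  cfg <- fixture$config
  tab <- assignCysLabels(fixture$alignment, fixture$windows,
                         threshold = cfg$threshold)
  anno <- annotations(fixture$proteins)
  subfam <- stats::setNames(anno$subfamily, anno$id)
  summ <- summarizeConservation(tab, subfam, nFamily = cfg$n_family)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeConservedTable(tab, file.path(out_dir, "conserved_cys.tsv"))
    shading <- shadeAlignment(fixture$alignment, cutoff = cfg$cutoff)
    writeShadedAlignment(fixture$alignment, shading,
                         file.path(out_dir, "shaded_alignment.txt"),
                         format = "text")
    writeShadedAlignment(fixture$alignment, shading,
                         file.path(out_dir, "shaded_alignment.html"),
                         format = "html")
  }
  list(conserved = tab, summary = summ)
}

#' Run the mutation-annotation and inference stage
#'
#' Annotates the mutation catalog against the conserved-cysteine table,
#' applies the common-mutant-phenotype rule for heterodimers and
#' partner-binding edges, and writes catalog, hypothesis and summary
#' files.
#'
#' @inheritParams runConservation
#' @param conserved Conserved-cysteine table; defaults to the fixture's
#'   transcribed table.
#' @return A list with `catalog`, `heterodimers`, `partner_edges` and
#'   `summary`.
#' @export
runInference <- function(fixture, conserved = fixture$conserved,
                         out_dir = NULL) {
  cfg <- fixture$config
  anno <- annotations(fixture$proteins)
  parsed <- parseMutationTable(fixture$mutations)
  if (nrow(parsed$errors))
    warning(nrow(parsed$errors), " malformed mutation rows skipped")
  catalog <- annotateCatalog(parsed$records, conserved, anno,
                             partnerDomains = fixture$partner_domains,
                             partnerIds = cfg$partners,
                             nearRegion = fixtureNearRegion(cfg),
                             synonyms = fixtureSynonyms(cfg))
  known <- fixtureKnownPairs(cfg)
  het <- proposeHeterodimers(catalog, anno, known)
  pe <- proposePartnerInteractions(catalog, anno, cfg$partners, known)
  summ <- summarizeHypotheses(het, pe)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeCatalog(catalog, file.path(out_dir, "mutation_catalog.tsv"))
    writeHypotheses(het, file.path(out_dir, "heterodimers"))
    writeHypotheses(pe, file.path(out_dir, "partner_edges"))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(catalog = catalog, heterodimers = het, partner_edges = pe,
       summary = summ)
}

#' Run the partner-domain stage
#'
#' Computes cysteine spacings of the configured binding pairs and of
#' mutated cysteines within each annotated partner domain, compares them
#' to the LTBP1 TGFB1-binding reference spacing, and classifies acidic
#' docking-site columns of the shipped TB-domain alignment.
#'
#' @inheritParams runInference
#' @param catalog Annotated catalog (computed from the fixture when
#'   `NULL`).
#' @return A list with `spacings` (data.frame), `docking`
#'   (classification data.frame) and `docking_counts`.
#' @export
runDomains <- function(fixture, catalog = NULL, out_dir = NULL) {
  cfg <- fixture$config
  ref_pair <- cfg$binding_pairs$ltbp1_tb3
  ref_spacing <- cysSpacing(ref_pair[1], ref_pair[2])
  tol <- cfg$spacing_tolerance
  rows <- list()
  for (nm in names(cfg$binding_pairs)) {
    pr <- cfg$binding_pairs[[nm]]
    sim <- spacingSimilarity(pr, ref_pair, tol)
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, kind = "binding_pair", partner = toupper(sub("_.*", "", nm)),
      pos_a = pr[1], pos_b = pr[2],
      spacing = cysSpacing(pr[1], pr[2]),
      similar_to_reference = sim$similar, delta = sim$delta,
      stringsAsFactors = FALSE)
  }
  if (is.null(catalog)) {
    parsed <- parseMutationTable(fixture$mutations)
    catalog <- annotateCatalog(parsed$records, fixture$conserved,
                               annotations(fixture$proteins),
                               partnerDomains = fixture$partner_domains,
                               partnerIds = cfg$partners,
                               nearRegion = fixtureNearRegion(cfg),
                               synonyms = fixtureSynonyms(cfg))
  }
  dom <- fixture$partner_domains
  for (i in seq_len(nrow(dom))) {
    hits <- catalog[catalog$protein == dom$partner[i] &
                      catalog$effect == "CYS_LOSS" &
                      catalog$position >= dom$start[i] &
                      catalog$position <= dom$end[i], , drop = FALSE]
    pos <- sort(unique(hits$position))
    if (length(pos) < 2L) next
    cmb <- utils::combn(pos, 2L)
    for (k in seq_len(ncol(cmb))) {
      sim <- spacingSimilarity(cmb[, k], ref_pair, tol)
      rows[[length(rows) + 1L]] <- data.frame(
        set = sprintf("%s_%s%d", dom$partner[i], dom$kind[i],
                      dom$ordinal[i]),
        kind = "mutated_pair", partner = dom$partner[i],
        pos_a = cmb[1L, k], pos_b = cmb[2L, k],
        spacing = cysSpacing(cmb[1L, k], cmb[2L, k]),
        similar_to_reference = sim$similar, delta = sim$delta,
        stringsAsFactors = FALSE)
    }
  }
  spacings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), kind = character(),
               partner = character(), pos_a = integer(),
               pos_b = integer(), spacing = integer(),
               similar_to_reference = logical(), delta = integer(),
               stringsAsFactors = FALSE)
  rownames(spacings) <- NULL
  docking <- dockingSiteCompare(fixture$docking, cfg$docking_reference)
  counts <- table(factor(docking$class,
                         levels = c("CONSERVED_ACIDIC_ALL",
                                    "REFERENCE_ONLY",
                                    "NONREFERENCE_ONLY", "NONE")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(spacings, file.path(out_dir, "cys_spacings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeDockingComparison(docking,
                           file.path(out_dir, "docking_columns.tsv"))
    writeDockingHtml(fixture$docking, docking,
                     file.path(out_dir, "docking_columns.html"))
  }
  list(spacings = spacings, docking = docking,
       docking_counts = counts)
}
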