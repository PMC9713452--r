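#' Canonical unordered pair keys
#'
#' @param a,b Character vectors of protein ids.
#' @return `"A|B"` with members sorted, vectorised.
#' @export
canonicalPair <- function(a, b) {
  mapply(function(x, y) paste(sort(c(x, y)), collapse = "|"), a, b,
         USE.NAMES = FALSE)
}

.qualifyingEvidence <- function(catalog, familyIds) {
  fam <- catalog$protein %in% familyIds & !is.na(catalog$phenotype_key)
  loss_cons <- catalog$effect == "CYS_LOSS" &
    catalog$context == "PRODOMAIN_CONSERVED"
  loss_lig <- catalog$effect == "CYS_LOSS" & catalog$context == "LIGAND"
  gain_near <- catalog$effect == "CYS_GAIN" & catalog$near_region
  catalog[fam & (loss_cons | loss_lig | gain_near), , drop = FALSE]
}

#' Propose heterodimer pairs from common mutant phenotypes
#'
#' Applies the common-mutant-phenotype rule: cysteine mutations in two
#' family proteins that produce the same disease phenotype point to a
#' lost shared interaction, here interpreted as a heterodimer.
#' Qualifying evidence for a protein under a phenotype is a cysteine
#' loss at a conserved prodomain position, a cysteine loss in the
#' ligand, or a curated cysteine gain topologically near a region.  For
#' each phenotype, every unordered pair of distinct qualifying proteins
#' is emitted.  When exactly one protein qualifies but does so at two or
#' more distinct positions (e.g. prodomain plus ligand), a homotypic
#' dimer hypothesis is emitted instead; heterotypic pairs take
#' precedence as the explanation of a shared phenotype, so no homotypic
#' pair is emitted alongside them.
#'
#' @param catalog Annotated catalog from [annotateCatalog()].
#' @param anno Family annotation `data.frame` (ids and subfamilies).
#' @param known Character vector of known interaction pair keys as from
#'   [canonicalPair()] (previously demonstrated interactions).
#' @return A `data.frame` of hypotheses with columns `kind`, `member1`,
#'   `member2`, `phenotype_key`, `support` (semicolon-joined mutation
#'   ids), `scope` (`WITHIN_SUBFAMILY`/`ACROSS_SUBFAMILY`), `subfamilies`
#'   and logical `novel`; sorted by phenotype then members.
#' @export
proposeHeterodimers <- function(catalog, anno, known = character()) {
  familyIds <- anno$id[anno$subfamily != "outgroup"]
  subfam <- stats::setNames(anno$subfamily, anno$id)
  ev <- .qualifyingEvidence(catalog, familyIds)
  out <- list()
  for (ph in sort(unique(ev$phenotype_key))) {
    sub <- ev[ev$phenotype_key == ph, , drop = FALSE]
    prots <- sort(unique(sub$protein))
    pairs <- list()
    if (length(prots) >= 2L) {
      cmb <- utils::combn(prots, 2L)
      for (k in seq_len(ncol(cmb)))
        pairs[[k]] <- cmb[, k]
    } else if (length(prots) == 1L &&
               length(unique(sub$position)) >= 2L) {
      pairs[[1L]] <- c(prots, prots)
    }
    for (pr in pairs) {
      supp <- sort(unique(sub$id[sub$protein %in% pr]))
      sf <- sort(unique(unname(subfam[pr])))
      out[[length(out) + 1L]] <- data.frame(
        kind = "HETERODIMER", member1 = pr[1L], member2 = pr[2L],
        phenotype_key = ph, support = paste(supp, collapse = ";"),
        scope = if (length(sf) == 1L) "WITHIN_SUBFAMILY" else
          "ACROSS_SUBFAMILY",
        subfamilies = paste(sf, collapse = "|"),
        novel = !canonicalPair(pr[1L], pr[2L]) %in% known,
        stringsAsFactors = FALSE)
    }
  }
  hyp <- if (length(out)) do.call(rbind, out) else .emptyHypotheses()
  hyp <- unique(hyp)
  hyp <- hyp[order(hyp$phenotype_key, hyp$member1, hyp$member2), ,
             drop = FALSE]
  rownames(hyp) <- NULL
  hyp
}

.emptyHypotheses <- function() {
  data.frame(kind = character(), member1 = character(),
             member2 = character(), phenotype_key = character(),
             support = character(), scope = character(),
             subfamilies = character(), novel = logical(),
             stringsAsFactors = FALSE)
}

#' Propose partner-protein binding interactions
#'
#' For each cysteine loss at a conserved prodomain position of a family
#' protein, every partner protein carrying at least one cysteine-loss
#' record with the same phenotype key yields one binding edge
#' (family protein, partner).  Edges are deduplicated on
#' (members, phenotype); the anchoring region(s) (`ASSN`/`B8`) of the
#' family mutation are recorded.
#'
#' @param catalog Annotated catalog.
#' @param anno Family annotation `data.frame`.
#' @param partnerIds Character vector of candidate partner proteins.
#' @param known Known interaction pair keys as from [canonicalPair()].
#' @return A hypothesis `data.frame` as for [proposeHeterodimers()] with
#'   `kind = "PARTNER_BINDING"`, `scope = "NA"` and an `anchor_region`
#'   column; sorted by phenotype then members.
#' @export
proposePartnerInteractions <- function(catalog, anno, partnerIds,
                                       known = character()) {
  familyIds <- anno$id[anno$subfamily != "outgroup"]
  anchors <- catalog[catalog$protein %in% familyIds &
                       catalog$effect == "CYS_LOSS" &
                       catalog$context == "PRODOMAIN_CONSERVED" &
                       !is.na(catalog$phenotype_key), , drop = FALSE]
  ploss <- catalog[catalog$protein %in% partnerIds &
                     catalog$effect == "CYS_LOSS" &
                     !is.na(catalog$phenotype_key), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    ph <- anchors$phenotype_key[i]
    fam <- anchors$protein[i]
    hits <- ploss[ploss$phenotype_key == ph, , drop = FALSE]
    for (partner in sort(unique(hits$protein))) {
      supp <- c(anchors$id[i], hits$id[hits$protein == partner])
      out[[length(out) + 1L]] <- data.frame(
        kind = "PARTNER_BINDING", member1 = fam, member2 = partner,
        phenotype_key = ph, support = paste(supp, collapse = ";"),
        scope = "NA", subfamilies = NA_character_,
        anchor_region = anchors$region[i],
        novel = !canonicalPair(fam, partner) %in% known,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    hyp <- .emptyHypotheses()
    hyp$anchor_region <- character()
    return(hyp)
  }
  hyp <- do.call(rbind, out)
  # merge anchors/support of duplicate (pair, phenotype) edges
  key <- paste(hyp$member1, hyp$member2, hyp$phenotype_key, sep = "\r")
  merged <- lapply(split(hyp, factor(key, levels = unique(key))),
                   function(d) {
    d1 <- d[1L, , drop = FALSE]
    d1$support <- paste(sort(unique(unlist(strsplit(d$support, ";")))),
                        collapse = ";")
    d1$anchor_region <- paste(sort(unique(d$anchor_region)),
                              collapse = "|")
    d1
  })
  hyp <- do.call(rbind, merged)
  hyp <- hyp[order(hyp$phenotype_key, hyp$member1, hyp$member2), ,
             drop = FALSE]
  rownames(hyp) <- NULL
  hyp
}

#' Summarise interaction hypotheses
#'
#' Headline counts tally distinct novel pairs only; non-novel hypotheses
#' are emitted upstream for validation but excluded here.  Homotypic
#' pairs count toward `WITHIN_SUBFAMILY`.
#'
#' @param heterodimers Output of [proposeHeterodimers()].
#' @param partnerEdges Output of [proposePartnerInteractions()]
#'   (optional).
#' @return A list with `novel_heterodimers`, `within_subfamily`,
#'   `across_subfamily`, `within_by_subfamily` (named counts),
#'   `novel_partner_edges` and `distinct_partners`.
#' @export
summarizeHypotheses <- function(heterodimers,
                                partnerEdges = NULL) {
  hd <- heterodimers[heterodimers$novel, , drop = FALSE]
  hd_pairs <- unique(data.frame(
    key = canonicalPair(hd$member1, hd$member2),
    scope = hd$scope, subfamilies = hd$subfamilies,
    stringsAsFactors = FALSE))
  within <- hd_pairs[hd_pairs$scope == "WITHIN_SUBFAMILY", , drop = FALSE]
  within_by <- table(within$subfamilies)
  res <- list(
    novel_heterodimers = nrow(hd_pairs),
    within_subfamily = nrow(within),
    across_subfamily = sum(hd_pairs$scope == "ACROSS_SUBFAMILY"),
    within_by_subfamily = stats::setNames(as.integer(within_by),
                                          names(within_by)),
    novel_partner_edges = 0L, distinct_partners = 0L)
  if (!is.null(partnerEdges) && nrow(partnerEdges)) {
    pe <- partnerEdges[partnerEdges$novel, , drop = FALSE]
    keys <- unique(canonicalPair(pe$member1, pe$member2))
    res$novel_partner_edges <- length(keys)
    res$distinct_partners <- length(unique(pe$member2))
  }
  res
}

#' Write hypotheses as JSON and TSV edge list
#'
#' @param hyp Hypothesis `data.frame`.
#' @param path Output path without extension; `<path>.json` and
#'   `<path>.tsv` are written.
#' @return Invisibly, the two paths.
#' @export
writeHypotheses <- function(hyp, path) {
  json <- paste0(path, ".json")
  tsv <- paste0(path, ".tsv")
  jsonlite::write_json(hyp, json, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  utils::write.table(hyp, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json, tsv))
}
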