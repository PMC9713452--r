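# In-code fixture builders and independent oracles shared across tests.

# Build a ProteinSet from plain character sequences.
makeProteins <- function(seqs, subfamily = "BMP", signal_end = NA,
                         cleavage = NULL) {
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(cleavage)) cleavage <- nchar(seqs) - 1L
  anno <- data.frame(
    id = ids, accession = paste0("T:", ids),
    subfamily = rep_len(subfamily, n),
    signal_start = ifelse(is.na(rep_len(signal_end, n)), NA, 1L),
    signal_end = rep_len(signal_end, n),
    cleavage_pos = rep_len(as.integer(cleavage), n),
    stringsAsFactors = FALSE)
  applyAnnotations(Biostrings::AAStringSet(seqs), anno)
}

# Build a ProdomainAlignment directly from gapped rows plus start offsets.
makeAln <- function(rows, start) {
  ng <- vapply(strsplit(rows, ""), function(x) sum(x != "-"), integer(1))
  makeAlignment(Biostrings::AAStringSet(rows), start = start,
                end = start + ng - 1L)
}

# Minimal annotated-catalog row constructor for inference tests.
catRow <- function(protein, position, effect, context, phenotype,
                   region = NA_character_, near = FALSE,
                   id = sprintf("%s_%d_%s", protein, position, effect)) {
  data.frame(id = id, protein = protein, position = position,
             effect = effect, context = context,
             phenotype_key = phenotype, region = region,
             near_region = near, stringsAsFactors = FALSE)
}

famAnno <- function(ids, subfamily) {
  data.frame(id = ids, subfamily = subfamily, stringsAsFactors = FALSE)
}

# Independent brute-force re-derivation of the heterodimer rule:
# plain nested loops over phenotypes and protein pairs.
bruteForceHeterodimers <- function(catalog, anno, known = character()) {
  familyIds <- anno$id[anno$subfamily != "outgroup"]
  qual <- rep(FALSE, nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    r <- catalog[i, ]
    if (!r$protein %in% familyIds || is.na(r$phenotype_key)) next
    if (r$effect == "CYS_LOSS" && r$context == "PRODOMAIN_CONSERVED")
      qual[i] <- TRUE
    if (r$effect == "CYS_LOSS" && r$context == "LIGAND") qual[i] <- TRUE
    if (r$effect == "CYS_GAIN" && isTRUE(r$near_region)) qual[i] <- TRUE
  }
  ev <- catalog[qual, , drop = FALSE]
  out <- NULL
  for (ph in sort(unique(ev$phenotype_key))) {
    prots <- sort(unique(ev$protein[ev$phenotype_key == ph]))
    if (length(prots) >= 2) {
      for (i in seq_along(prots)) for (j in seq_along(prots)) {
        if (i < j) {
          out <- rbind(out, data.frame(
            member1 = prots[i], member2 = prots[j], phenotype_key = ph,
            novel = !paste(sort(c(prots[i], prots[j])), collapse = "|") %in%
              known,
            stringsAsFactors = FALSE))
        }
      }
    } else if (length(prots) == 1) {
      pos <- unique(ev$position[ev$phenotype_key == ph])
      if (length(pos) >= 2) {
        out <- rbind(out, data.frame(
          member1 = prots, member2 = prots, phenotype_key = ph,
          novel = !paste(c(prots, prots), collapse = "|") %in% known,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    return(data.frame(member1 = character(), member2 = character(),
                      phenotype_key = character(), novel = logical(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$phenotype_key, out$member1, out$member2), ]
  rownames(out) <- NULL
  out
}

# Independent brute-force partner-edge derivation.
bruteForcePartnerEdges <- function(catalog, anno, partnerIds) {
  familyIds <- anno$id[anno$subfamily != "outgroup"]
  out <- NULL
  for (i in seq_len(nrow(catalog))) {
    a <- catalog[i, ]
    if (!a$protein %in% familyIds) next
    if (a$effect != "CYS_LOSS" || a$context != "PRODOMAIN_CONSERVED") next
    if (is.na(a$phenotype_key)) next
    for (p in partnerIds) {
      hit <- FALSE
      for (j in seq_len(nrow(catalog))) {
        b <- catalog[j, ]
        if (b$protein == p && b$effect == "CYS_LOSS" &&
            !is.na(b$phenotype_key) &&
            b$phenotype_key == a$phenotype_key) hit <- TRUE
      }
      if (hit)
        out <- rbind(out, data.frame(member1 = a$protein, member2 = p,
                                     phenotype_key = a$phenotype_key,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(member1 = character(), member2 = character(),
                      phenotype_key = character(), stringsAsFactors = FALSE))
  out <- unique(out)
  out <- out[order(out$phenotype_key, out$member1, out$member2), ]
  rownames(out) <- NULL
  out
}

# Random alignment generator for property tests (fixed seed set by caller).
randomAln <- function(n_rows, width, cys_rate = 0.15, gap_rate = 0.1) {
  pool <- setdiff(c("A", "G", "L", "S", "T", "V", "N", "Q", "C"), NULL)
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(pool, width, replace = TRUE)
    chars[stats::runif(width) < cys_rate] <- "C"
    gaps <- stats::runif(width) < gap_rate
    gaps[1] <- FALSE  # keep at least one residue
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, "")
  names(rows) <- sprintf("R%02d", seq_len(n_rows))
  makeAln(rows, start = stats::setNames(rep(1L, n_rows), names(rows)))
}
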