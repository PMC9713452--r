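#' Configuration for the synthetic family generator
#'
#' The defaults emulate the human family under study: 33 proteins in
#' three subfamilies (8 TGF-beta-like, 8 Activin-like, 17 BMP-like),
#' prodomains of about 250 residues behind a 25-residue signal peptide,
#' a 4-column Association window near the amino terminus and a 4-column
#' beta-8 window near the carboxy terminus.  Sequences are drawn from a
#' uniform background over the 19 non-cysteine residues so that planted
#' cysteine columns are unambiguous; `bg_cys_rate` can reintroduce
#' background cysteines for stress tests, and `indel = TRUE` draws
#' per-protein prodomain lengths from `len_range` and places the
#' compensating gap block away from the windows to exercise coordinate
#' mapping.
#'
#' @param subfamily_sizes Named integer vector of proteins per subfamily.
#' @param len_range Prodomain length range (gap-free default uses the
#'   maximum for every protein).
#' @param signal_len Signal peptide length.
#' @param assn_cols,b8_cols Planted cysteine columns, given as offsets
#'   0/2/3 from each window anchor; windows are placed at columns
#'   11-14 and `max(len_range)` - 19 .. - 16.
#' @param assn_carriers,b8_carriers Fraction of proteins carrying a
#'   planted cysteine at each region's columns (carriers are the first
#'   `ceiling(fraction * n)` proteins, so truth is derivable from the
#'   configuration).
#' @param planted_pairs `data.frame` with columns `a`, `b`, `phenotype`:
#'   interaction pairs to plant via shared-phenotype cysteine-loss
#'   mutations at conserved positions (protein indices or ids).
#' @param n_noise Number of noise mutations, each with a singleton
#'   phenotype.
#' @param bg_cys_rate Background cysteine rate outside planted columns.
#' @param indel Logical; enable the indel mode.
#' @param threshold Conservation threshold the truth bundle assumes.
#' @param seed Random seed fixing all randomness.
#' @return A list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(subfamily_sizes = c("TGF-beta" = 8L,
                                                "Activin" = 8L,
                                                "BMP" = 17L),
                            len_range = c(200L, 250L),
                            signal_len = 25L,
                            assn_cols = c(0L, 3L), b8_cols = c(0L, 2L, 3L),
                            assn_carriers = 0.5, b8_carriers = 0.6,
                            planted_pairs = NULL, n_noise = 0L,
                            bg_cys_rate = 0, indel = FALSE,
                            threshold = 0.2, seed = 1L) {
  stopifnot(all(assn_cols %in% c(0L, 2L, 3L)),
            all(b8_cols %in% c(0L, 2L, 3L)))
  L <- max(len_range)
  cfg <- list(subfamily_sizes = subfamily_sizes, len_range = len_range,
              signal_len = as.integer(signal_len),
              width = as.integer(L),
              assn_window = c(11L, 14L),
              b8_window = c(L - 19L, L - 16L),
              assn_cols = as.integer(assn_cols),
              b8_cols = as.integer(b8_cols),
              assn_carriers = assn_carriers, b8_carriers = b8_carriers,
              planted_pairs = planted_pairs, n_noise = as.integer(n_noise),
              bg_cys_rate = bg_cys_rate, indel = indel,
              threshold = threshold, seed = as.integer(seed))
  if (cfg$b8_window[1L] <= cfg$assn_window[2L] + 1L)
    stop("prodomain too short for disjoint region windows")
  class(cfg) <- "syntheticConfig"
  cfg
}

.nonCysResidues <- setdiff(AA_STANDARD, "C")

#' Generate a synthetic protein family with planted ground truth
#'
#' Produces precursor records, a prodomain alignment, a mutation table
#' and the truth bundle (expected conserved-cysteine table and expected
#' interaction hypotheses).  The same configuration and seed always
#' yield identical outputs.
#'
#' @param cfg A [syntheticConfig()].
#' @return A list with elements `proteins` ([ProteinSet-class]),
#'   `alignment` ([ProdomainAlignment-class]), `mutations` (`data.frame`
#'   in the mutation-table layout), and `truth` (list with `conserved`
#'   and `pairs`).
#' @export
generateFamily <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  set.seed(cfg$seed)
  n <- sum(cfg$subfamily_sizes)
  empty <- list(
    proteins = NULL, alignment = NULL,
    mutations = data.frame(protein = character(), position = integer(),
                           ref = character(), alt = character(),
                           phenotype = character(), source = character(),
                           stringsAsFactors = FALSE),
    truth = list(conserved = data.frame(protein = character(),
                                        region = character(),
                                        position = integer(),
                                        label = character(),
                                        stringsAsFactors = FALSE),
                 pairs = data.frame(member1 = character(),
                                    member2 = character(),
                                    phenotype_key = character(),
                                    stringsAsFactors = FALSE)))
  if (n == 0L) return(empty)
  ids <- sprintf("SYN%02d", seq_len(n))
  subfam <- rep(names(cfg$subfamily_sizes), cfg$subfamily_sizes)
  W <- cfg$width
  windows <- list(ASSN = cfg$assn_window, B8 = cfg$b8_window)
  planted <- list(ASSN = cfg$assn_window[1L] + cfg$assn_cols,
                  B8 = cfg$b8_window[1L] + cfg$b8_cols)
  carriers <- list(
    ASSN = seq_len(max(0L, ceiling(cfg$assn_carriers * n))),
    B8 = seq_len(max(0L, ceiling(cfg$b8_carriers * n))))

  # gapped rows: template of width W, indel mode gaps a block per protein
  rows <- character(n)
  for (i in seq_len(n)) {
    chars <- sample(.nonCysResidues, W, replace = TRUE)
    if (cfg$bg_cys_rate > 0) {
      hit <- stats::runif(W) < cfg$bg_cys_rate
      hit[c(planted$ASSN, planted$B8)] <- FALSE
      hit[cfg$assn_window[1L]:cfg$assn_window[2L]] <- FALSE
      hit[cfg$b8_window[1L]:cfg$b8_window[2L]] <- FALSE
      chars[hit] <- "C"
    }
    for (region in names(planted))
      if (i %in% carriers[[region]]) chars[planted[[region]]] <- "C"
    if (cfg$indel) {
      len <- sample(seq(cfg$len_range[1L], cfg$len_range[2L]), 1L)
      ndel <- W - len
      if (ndel > 0L) {
        gap_zone <- (cfg$assn_window[2L] + 2L):(cfg$b8_window[1L] - 2L -
                                                  ndel)
        at <- sample(gap_zone, 1L)
        chars[at:(at + ndel - 1L)] <- "-"
      }
    }
    rows[i] <- paste(chars, collapse = "")
  }
  names(rows) <- ids

  sig_len <- cfg$signal_len
  prodoms <- gsub("-", "", rows, fixed = TRUE)
  start <- rep(sig_len + 1L, n)
  end <- sig_len + nchar(prodoms)
  names(start) <- names(end) <- ids
  signal <- vapply(seq_len(n), function(i)
    paste(sample(.nonCysResidues, sig_len, replace = TRUE),
          collapse = ""), "")
  ligand <- vapply(seq_len(n), function(i)
    paste(sample(.nonCysResidues, 20L, replace = TRUE), collapse = ""),
    "")
  precursors <- Biostrings::AAStringSet(paste0(signal, prodoms, ligand))
  names(precursors) <- ids
  anno <- data.frame(id = ids, accession = paste0("SYN:", ids),
                     subfamily = subfam, signal_start = 1L,
                     signal_end = sig_len, cleavage_pos = unname(end),
                     stringsAsFactors = FALSE)
  pset <- applyAnnotations(precursors, anno)
  aln <- makeAlignment(Biostrings::AAStringSet(rows),
                       pdoms = extractProdomains(pset))

  # truth: conserved table from the planted design
  truth_rows <- list()
  labels <- c("0" = "CYS@1", "2" = "CYS@3", "3" = "CYS@4")
  for (region in names(planted)) {
    cols <- planted[[region]]
    carr <- carriers[[region]]
    conserved_cols <- cols[length(carr) / n >= cfg$threshold]
    if (!length(conserved_cols)) next
    anchor <- min(conserved_cols)
    for (col in cols) {
      off <- col - anchor
      if (!as.character(off) %in% names(labels)) next
      for (i in carr) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          protein = ids[i], region = region,
          position = columnToResidue(aln, ids[i], col),
          label = labels[[as.character(off)]], stringsAsFactors = FALSE)
      }
    }
  }
  truth_cons <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    empty$truth$conserved
  truth_cons <- truth_cons[order(truth_cons$protein, truth_cons$region,
                                 truth_cons$position), , drop = FALSE]
  rownames(truth_cons) <- NULL

  # planted interaction mutations + noise
  muts <- list()
  pairs <- cfg$planted_pairs
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      for (p in c(pairs$a[k], pairs$b[k])) {
        pid <- if (is.numeric(p)) ids[p] else p
        pos <- truth_cons$position[truth_cons$protein == pid][1L]
        if (is.na(pos))
          stop("planted pair member ", pid, " carries no conserved cysteine")
        muts[[length(muts) + 1L]] <- data.frame(
          protein = pid, position = pos, ref = "C", alt = "R",
          phenotype = pairs$phenotype[k], source = "synthetic",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (cfg$n_noise > 0L) {
    cons_prot <- unique(truth_cons$protein)
    for (k in seq_len(cfg$n_noise)) {
      pid <- cons_prot[((k - 1L) %% length(cons_prot)) + 1L]
      pos <- truth_cons$position[truth_cons$protein == pid][1L]
      muts[[length(muts) + 1L]] <- data.frame(
        protein = pid, position = pos, ref = "C", alt = "Y",
        phenotype = sprintf("noise phenotype %03d", k),
        source = "synthetic", stringsAsFactors = FALSE)
    }
  }
  mutations <- if (length(muts)) do.call(rbind, muts) else
    empty$mutations

  truth_pairs <- if (!is.null(pairs) && nrow(pairs)) {
    a <- if (is.numeric(pairs$a)) ids[as.integer(pairs$a)] else
      as.character(pairs$a)
    b <- if (is.numeric(pairs$b)) ids[as.integer(pairs$b)] else
      as.character(pairs$b)
    m1 <- pmin(a, b)
    m2 <- pmax(a, b)
    ph <- normalizePhenotype(pairs$phenotype)
    d <- data.frame(member1 = m1, member2 = m2, phenotype_key = ph,
                    stringsAsFactors = FALSE)
    d <- d[order(d$phenotype_key, d$member1, d$member2), , drop = FALSE]
    rownames(d) <- NULL
    d
  } else empty$truth$pairs

  list(proteins = pset, alignment = aln, mutations = mutations,
       truth = list(conserved = truth_cons, pairs = truth_pairs),
       windows = list(regionWindow("ASSN", cfg$assn_window[1L],
                                   cfg$assn_window[2L]),
                      regionWindow("B8", cfg$b8_window[1L],
                                   cfg$b8_window[2L])))
}

#' Write a generated family to a directory
#'
#' Writes `precursors.fasta`, `annotations.tsv`,
#' `prodomain_alignment.fasta` (headers with `|start-end` suffixes) and
#' `mutations.tsv` in the same layout as the packaged fixture.
#'
#' @param fam Output of [generateFamily()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeFamily <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(fam$proteins)) {
    Biostrings::writeXStringSet(precursors(fam$proteins),
                                file.path(dir, "precursors.fasta"))
    utils::write.table(annotations(fam$proteins),
                       file.path(dir, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    aln <- alignedRows(fam$alignment)
    names(aln) <- sprintf("%s|%d-%d", names(aln),
                          prodomainStart(fam$alignment),
                          prodomainEnd(fam$alignment))
    Biostrings::writeXStringSet(aln,
                                file.path(dir,
                                          "prodomain_alignment.fasta"))
  }
  utils::write.table(fam$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
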