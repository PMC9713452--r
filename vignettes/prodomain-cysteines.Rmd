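---
title: "Conserved prodomain cysteines and common-phenotype interaction inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved prodomain cysteines and common-phenotype interaction inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prodomainCys)
```

## Background

The 33 human TGF-beta family proteins are synthesised as three-part
precursors: a signal peptide, a roughly 250-residue prodomain, and the
carboxy-terminal ligand.  Two disulfide-dependent regulatory mechanisms
act through prodomain cysteines: dimerisation, mediated by cysteines in
the beta-8 region near the prodomain/ligand cleavage site, and latency
through partner-protein binding (LTBP, fibrillin, LRC32/GARP, LRC33,
SELE), mediated by a cysteine in the Association (Assn) region near the
amino terminus.  For most family members the participating cysteines
are unknown.  This package implements a desk-scale comparative pipeline
that (i) detects conserved cysteine columns in a trimmed prodomain
alignment, (ii) names them positionally, (iii) intersects them with
cysteine-affecting disease mutations, and (iv) applies the
common-mutant-phenotype rule -- mutations in two proteins that produce
the same disease phenotype point to a lost shared biochemical
interaction -- to propose heterodimer pairs and partner-binding edges.

## Coordinates and trimming

All positions are 1-based precursor coordinates with Met1 = 1, because
every position quoted in the literature of this family (TGFB1 Cys33,
Cys223/225, TGFB2 Cys254/256/257, INHBA Cys244/247, ...) is a precursor
coordinate.  The signal peptide and ligand are removed before
alignment, but each `ProdomainSet`/`ProdomainAlignment` row carries its
precursor offset so alignment columns map losslessly back to precursor
positions (`columnToResidue()` / `residueToColumn()`, which round-trip
for every non-gap cell).

## Conservation model

Column shading follows the BoxShade tradition: residues are partitioned
into biochemical similarity groups (defaults: FYW, ILVM, RK, DE, ST,
NQ, and singletons A, G, P, C, H; configurable), and a cell is shaded
when its group's frequency in the column reaches the cutoff.  The
plurality residue of the group is shaded as identity, other group
members as similar.  Two deliberate choices:

* **Gaps count in the denominator.**  A cysteine present in 7 of 33
  proteins is conserved at the 20% cutoff whether or not other rows are
  gapped there; absent proteins dilute conservation.  This matches
  shading of a fixed-size family figure.
* **The threshold is closed (`>=`) and defaults to 0.2** for both
  identity and similarity, each independently configurable -- the
  permissive 20% level is what makes minority-subfamily cysteines
  (present in, say, 7 of 33 rows) visible at all.

Conserved cysteine columns inside each 4-column region window receive
positional labels measured in alignment columns from the window's first
conserved column (the anchor): `CYS@1` at the anchor, `CYS@3` at anchor
+ 2, `CYS@4` at anchor + 3.  Offsets are columns, not ungapped
residues, so proteins with local indels still receive comparable
labels.  The region windows themselves are configuration: they encode
the structure-guided placement of the beta-8 and Assn regions, which is
a manual, structure-informed judgment that the pipeline consumes rather
than reproduces.

## Mutation catalog

Mutation records (protein, precursor position, reference and alternate
residue, free-text phenotype, source database) are classified as
cysteine loss (C to anything, including stops and in-frame deletions
starting at the cysteine), cysteine gain (anything to C), or other.
Phenotype strings are normalised conservatively -- lowercase, trimmed,
whitespace-collapsed, plus an explicit synonym map -- and matched
exactly.  Fuzzy matching is deliberately avoided because the source
databases distinguish tumour cell types (squamous-cell versus
adenocarcinoma) that must not merge.  Each record is annotated with its
feature context: a conserved prodomain position, another prodomain
site, the ligand (positions beyond the cleavage site), an annotated
partner domain, or unmapped.

## Inference rules

Qualifying heterodimer evidence for a protein under a phenotype is any
of: a cysteine loss at a conserved prodomain position, a cysteine loss
in the ligand (which corroborates the prodomain position when the
phenotypes agree), or a curated cysteine gain topologically near a
region (a structural judgment shipped as configuration, e.g. INHBB
Ser154Cys near the Assn cysteine pair).  For each phenotype every
unordered pair of qualifying proteins becomes a hypothesis; pairs in
the configured known-interaction set are emitted but flagged
non-novel.

**Homotypic rule (a genuinely open design point).**  When exactly one
protein qualifies for a phenotype but does so at two or more distinct
positions (prodomain plus ligand, or two conserved positions), we emit
a homotypic dimer hypothesis; when any heterotypic partner shares the
phenotype we do not.  The heterotypic pair is the more parsimonious
explanation of a phenotype shared across proteins, and a homotypic
reading alongside it would double-count the same evidence.  Under this
rule the catalogued phenotype groups close exactly to the published
arithmetic: four within-subfamily pairs (one BMP, one Activin, two
TGF-beta, including the TGFB2 homodimer from the Holt-Oram group),
three across-subfamily pairs (all Activin with TGF-beta), and the
TGFB1 homodimer from the Camurati-Engelmann group suppressed as
already known.

Partner-binding edges require a cysteine loss at a conserved prodomain
position on the family side and at least one cysteine loss with the
same phenotype key on the partner side; every such (family, partner)
pair is one edge, deduplicated on members and phenotype, with the
anchoring region (Assn or beta-8) recorded.

## The packaged fixture

No accessions or alignments are deposited for this analysis, so the
package ships a transcription fixture: the mutation catalog, partner
domains, known-interaction set and conserved-cysteine table are
transcribed from the published tables and results text (each row
carries a provenance tag: `results-text`, `table-transcription`, or
`synthetic` for positions the text does not state), while the precursor
sequences and the prodomain alignment are constructed stand-ins that
honour every published precursor coordinate and contain no cysteines
outside the designed columns.  Two transcription choices are worth
flagging: the fifth colon-adenocarcinoma partner of GDF6 is not named
in the results text and is carried as LTBP2 with provenance
`table-transcription`; and TGFB2 Cys246, described as a ligand residue,
lies amino-terminal to TGFB2's own beta-8 cysteines and is therefore
classified `PRODOMAIN_OTHER` (non-qualifying) -- the lung
adenocarcinoma pairing is carried by Cys407Ser, so no counted result
depends on it.

```{r fixture}
fx <- loadStudyFixture()
res <- runConservation(fx)
res$summary$per_region
res$summary$overall
```

```{r inference}
inf <- runInference(fx)
inf$summary[c("novel_heterodimers", "within_subfamily",
              "across_subfamily", "novel_partner_edges",
              "distinct_partners")]
```

## The synthetic generator

`generateFamily()` is the package's controlled test bed.  Its defaults
are the study conditions: 33 proteins in the 8/8/17 subfamily split,
prodomains of 200-250 residues behind a 25-residue signal, 4-column
Assn and beta-8 windows, and planted cysteine columns at the `CYS@1` /
`CYS@3` / `CYS@4` offsets with configurable carrier fractions.
Background residues are drawn uniformly over the 19 non-cysteine
residues so planted conservation is unambiguous (a `bg_cys_rate` flag
reintroduces background cysteines for stress tests); the default
alignment is gap-free, and an indel mode draws per-protein lengths and
places the compensating gap block away from the windows to exercise
coordinate mapping.  Planted interaction pairs receive cysteine-loss
mutations sharing a unique phenotype; noise mutations receive singleton
phenotypes and therefore cannot create pairs.  What passing these tests
shows is that the detector and the inference engine are exact on data
matching their assumptions; what it does not show is robustness to real
evolutionary alignments, alignment error, or phenotype-vocabulary noise
across databases -- the fixture-side tests cover the one realisation of
those that the study itself analysed.

Problem sizes used in the test suite are deliberately small (10-14
proteins, 60-90-column prodomains, 20 seeds for the recovery
properties), which keeps the whole suite in the tens of seconds while
still exercising every rule; the full 33-protein fixture path runs in
well under a second.

## Partner-domain comparisons

`cysSpacing()` is the absolute precursor distance, the convention that
reproduces the published 25 (LTBP1 Cys1359/1384), 35 (LTBP1
Cys559/594) and 139 (LRC32 Cys211/350) residue spacings.  (The
alternative 1359/1384 coordinates are used for LTBP1's TGFB1-binding
pair; the Cys1539/1584 variant appearing elsewhere is arithmetically
inconsistent with its own stated 25-residue spacing.)  The default
spacing tolerance of 5 residues makes the 27- and 28-residue candidate
pairs similar to the 25-residue reference while 35 and 139 are not.
`dockingSiteCompare()` classifies acidic (D/E) columns of aligned
TB/EGF domains against a reference row into conserved-in-all,
reference-only, non-reference-only and none; the two-residue FP
insertion unique to LTBP1's TGFB1-binding domain is reported
descriptively (`referenceInsertionColumns()`) rather than scored, since
only its presence or absence matters.

## Numerical and degenerate-input choices

* Plurality ties in shading break alphabetically; hypothesis output is
  sorted lexicographically by phenotype then members, and support ids
  are sorted -- all output files are byte-stable across reruns.
* Empty inputs are answers, not errors: a window without conserved
  columns yields an empty table section, an empty mutation table yields
  zero hypotheses, malformed catalog rows are collected into an error
  report while valid rows proceed.
* `X` residues are tolerated in sequences but belong to no similarity
  group and never shade.
* Fixture integrity is protected by MD5 checksums in a MANIFEST;
  loading fails loudly on any edit.

## Limitations

The pipeline consumes an externally computed alignment and curated
region windows; it does not align, nor discover windows from structure.
Phenotype co-occurrence is combinatorial, not statistical -- no
significance is attached to a shared phenotype, mirroring the
qualitative character of the underlying inference rule.  Expression
compatibility of proposed partners is not modelled.  The stand-in
fixture sequences reproduce published coordinates, not published
sequences; analyses of residues the text does not state are synthetic
by construction and tagged as such.
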