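---
title: "Methods: screening and characterizing putative TAG lipases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and characterizing putative TAG lipases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipscreen)
```

## The screening model

Triacylglycerol lipases across the families considered here share a
catalytic serine presented either by the central G-X₁-S-X₂-G
pentapeptide of the α/β-hydrolase fold (α/β hydrolases, class 3
lipases, patatin-like phospholipases) or by an N-terminal GDS(L) motif
(GDSL lipases). The funnel implemented in `run_screen()` operationalizes
this biology as a sequence of falsifiable filters, each recording its
exclusion reason per protein:

1. keyword match in the annotation description (case-insensitive), with
   a forced-include list for candidates known from prior studies;
2. minimum domain-hit E-value strictly below the threshold
   (default 10⁻⁵). *Strict* `<` was chosen because "threshold" in the
   source procedure is phrased as `E-value < 1e-5`; a hit exactly at the
   boundary is excluded. When a protein has several domain hits, the
   minimum decides — the most significant hit is the operative evidence;
3. motif requirement: at least one pentapeptide window (all overlapping
   windows are reported; downstream summaries keep the first per
   protein, as no tie rule is biologically defined), or for
   GDSL-flagged candidates at least one GDS match. The GDE variant,
   lacking the catalytic serine, fails this stage ("missing catalytic
   serine") — an inactive enzyme is not a candidate;
4. exclusion of proteins whose best homolog carries a precise
   non-lipase function. An *empty* best-homolog field retains the
   protein with a warning: absence of evidence is not evidence of a
   competing function;
5. family assignment by a configurable first-match rule table over
   description and domain names, defaulting to α/β hydrolase with a
   warning — the most inclusive family — when no rule fires.

The audit trail satisfies a partition invariant (every input protein
appears exactly once; per-stage exclusions plus final retained equal
the input count) and is byte-deterministic, both enforced by tests.

## Motif grammars

Motif wildcards ("X") match only the 20 standard residues, never the
ambiguity letters X/B/Z/U: a catalytic-context position must be a real
residue. Targeting signals are anchored: the ER-retention signal
`[K/D]-[D/E]-E-L` only as the last four residues, PTS1
`[S/A/C]-[K/R/H]-[L/M]` only as the last three. PTS2 (`S-S-L`) is
anchored C-terminally by default, following the screening procedure
this package models literally; because PTS2 is conventionally
N-terminal, `scan_targeting_signals(pts2_anchor = "N")` searches the
first 30 residues instead. Di-leucine sorting motifs
(`[D/E]XXXL[L/I]` or `DXXLL`) are reported anywhere, but on their own
never imply vacuolar localization — the localization rules additionally
require a signal peptide.

The GDS(L) N-terminal window defaults to the first 25% of the sequence
(configurable); the source procedure says only "N-terminal domain", and
25% is a conservative reading that still accepts domains displaced by
short pre-sequences.

## Physico-chemical panel

All constants follow the ProtParam conventions: average residue masses,
Kyte–Doolittle hydropathy, the Guruprasad dipeptide instability weights
(threshold 40 for the unstable class), the Ikai aliphatic index
(threshold 80 for likely thermostability), Gill–von Hippel extinction
coefficients and the N-end-rule half-life table. The tables are
embedded in `R/constants.R` and were verified against an independent
implementation (Biopython 1.88) on fixture sequences to exact
agreement; those frozen values are asserted in the test suite.

The isoelectric point is the unique zero of the Henderson–Hasselbalch
net charge with the Bjellqvist pKa set, found by bisection on [0, 14]
to 10⁻³ pH. Two subtleties of this pKa set are worth knowing:

* the N- and C-terminal pKa values are *residue-specific* (e.g. Cterm
  4.55 when the last residue is D). Consequently pI is permutation
  invariant only with the terminal residues held fixed, and the
  intuitive monotonicity "appending K never decreases pI / appending D
  never increases it" holds only up to ~0.01 pH: appending a residue
  also swaps the terminal pKa. The property tests carry 0.02 pH slack
  for exactly this reason;
* ambiguity letters are excluded from sums and means with a warning in
  the default lenient mode (`mode = "strict"` errors instead) — genome
  annotations occasionally contain X and the panel should not silently
  fabricate a mass or hydropathy for it.

Reported precision matches common practice: MW and pI to 2 decimals,
GRAVY to 3.

## Localization rules

External predictors (plastid, mitochondrial, signal-peptide,
transmembrane) are consumed as a table, never re-implemented. The
decision tree applies a fixed precedence — plastid > mitochondrion >
secretory > membrane > peroxisome > cytosol — yielding exactly one of
seven compartments per protein. This precedence is an explicit
reconstruction (the source pipeline's exact tree is not published in
its main text) and is deliberately configurable at the evidence level:
multiple signal-peptide predictor columns (`sp_*`) are arbitrated by
majority with ties positive, and the mitochondrial cutoff defaults to
0.85, a MitoProt-style convention. The vacuole is never emitted as a
compartment: proteins with both a signal peptide and a di-leucine motif
are flagged `vacuole_candidate` (possible lipophagy actors) while
keeping their ER call.

## Regulation ranking

Each gene's summary is the *signed* value of maximal absolute log2 fold
change across all datasets and timepoints. Exact opposite-sign ties are
flagged ambiguous and resolved toward the lexicographically earliest
dataset label — an explicit but arbitrary rule, exposed in the output so
downstream users can treat ambiguous genes separately. Band thresholds
(1 and 2) are strict. The summary also reports each gene's min and max
signed values as a dispersion diagnostic: a merged gene model whose two
halves are regulated differently shows up as a wide min–max interval.

## Structure QC

Dihedrals use the standard atan2 formulation and sign convention; tests
verify invariance under random rigid motions and sign flip under
mirroring. The default Ramachandran region map is a coarse analytic
10°×10° three-class partition (α and β/PPII cores as "highly favored", a
surrounding halo plus the left-handed α region as "favored", everything
else "questionable"); the authoritative web-server boundaries are
unpublished, so the map is pluggable — any 36×36 label matrix can be
supplied — and published questionable-fractions are only reproducible
with the same map, a known limitation. Glycine and proline use the same
map by default. pLDDT is read from the PDB B-factor column with bands
at 50/70/90; the rolling mean (default window 40) is centered with
shrunken edge windows.

## The synthetic world

The generators emit exactly the formats the readers parse, with ground
truth recorded at construction:

* backgrounds for motif-planting draw from an 18-letter alphabet
  without G and S, making chance pentapeptide or GDS matches
  impossible, so recall/precision statements are exact;
* the screening world used in the acceptance tests has 57 retained
  candidates (24 α/β hydrolases, 18 class 3, 7 GDSL, 8 patatin-like,
  after one inactive GDE-variant GDSL is excluded), the nine reported
  regulation magnitudes (−3.35 … 3.41) planted into nine genes, and a
  35 cytosol / 9 ER-cytosol / 13 organellar compartment split — the
  published funnel's shape, not its database-dependent raw counts,
  which are declared out of reproducible scope;
* regulation tables plant the intended signed maximum at one
  (dataset, timepoint) cell and keep all other cells strictly smaller
  in absolute value (≤ 0.95·|max| even under noise), so the planted
  maximum is recovered exactly by construction;
* backbone chains are built by internal-coordinate (NeRF) placement
  with fixed bond geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
  ω = 180°), so measured dihedrals equal the build values to below
  10⁻⁴ degrees in memory. PDB files quantize coordinates to 0.001 Å,
  limiting file-round-trip dihedral agreement to ~0.1°.

What a green suite establishes: the pipeline's logic recovers planted
truth exactly and its numerics agree with independent oracles. What it
does not establish: performance on real proteomes — synthetic sequences
have no homology structure, no alignment uncertainty, and predictor
tables with controlled rather than realistic error modes.

## Known limitations

* The Ramachandran map is coarse; absolute region percentages from
  high-resolution census maps will differ.
* The "Y" oxyanion-hole class is recognized in the type enumeration but
  has no detection rule (none is defined in the literature this
  models); such cases return `unknown`.
* Family assignment depends entirely on the configured rule table;
  annotation vocabularies differ across genomes.
* No normalization or differential-expression estimation is performed
  on regulation inputs — log2 fold changes are consumed as published.
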