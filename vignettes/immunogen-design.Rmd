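---
title: "Methods: scoring, uniqueness, conservation and feature overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, uniqueness, conservation and feature overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopep)
```

`immunopep` helps choose synthetic peptide immunogens for raising
antibodies against linear epitopes in relatively disordered regions of a
target protein. This vignette is the package's own account of the methods:
the scoring model and its assumptions, every tunable parameter, the
declared behaviour of the synthetic-data generator, the numerical
conventions, and the places where the design was genuinely open and a
choice had to be made.

## The immunogenicity model

Antibodies raised against short peptides recognise their target best when
the peptide corresponds to a surface-exposed, flexible stretch of the
native protein. Two classic per-residue propensity scales proxy this from
sequence alone: the Kyte–Doolittle hydropathy index (hydrophilic
stretches, with strongly negative values, tend to be solvent-exposed) and
the Chou–Fasman beta-turn conformational parameter `Pt` (turn-prone
stretches tend to be flexible loops rather than buried regular
structure). Terminal tails add a third, topological signal: free N- and
C-termini are disproportionately accessible and disordered, and
antibodies against terminal peptides have a strong practical track
record.

Each window of the chosen peptide length `L` receives

$$\mathrm{Ig} = 10 \cdot H \cdot T \cdot B$$

with

* $H = \mathrm{clamp}\big((4.5 - \overline{KD})/9,\ 0,\ 1\big)$, where
  $\overline{KD}$ is the window's mean Kyte–Doolittle value. The constants
  4.5 and 9 are the maximum and the span of the scale, so $H$ maps the
  most hydrophobic possible window to 0 and the most hydrophilic
  (poly-arginine) to 1.
* $T = \mathrm{clamp}\big((\overline{Pt} - 0.47)/1.09,\ 0,\ 1\big)$, where
  0.47 (Ile) and 1.56 (Asn/Gly) bound `Pt` over the 20 residues.
* $B$ = `tail_bonus` if the window lies *entirely* within `tail_length`
  residues of either terminus, else 1. Whole-window containment, rather
  than mere overlap, keeps the rule unambiguous and testable.

The product form encodes that a good immunogen should be hydrophilic
*and* turn-prone *and* (preferably) terminal — a window that fails any
factor badly cannot compensate with the others. The factor 10 puts
typical good windows into a single-digit band with 7 as the
high-immunogenicity threshold; with the default bonus the score is
bounded by $10B = 20$. Windows are ranked by competition ranking (tied
scores share the smallest rank; the next distinct score's rank is one
plus the number of strictly better windows).

This normalized product is this package's concrete instantiation of a
"product of hydropathy, turn propensity and tail bonus" score. It was
calibrated once against a published worked example — the rat aquaporin-2
C-terminal peptide `EPDTDWEEREVRRRQ`, which must score in the high band —
and the defaults were then frozen:

```{r}
ig_score("EPDTDWEEREVRRRQ", 1, 15, design_params(15))[
  , c("hydrophilicity", "turn_propensity", "tail_bonus", "ig_score")
]
```

Whether the historical score rescaled its raw product, and whether its
tail bonus was additive or multiplicative and how long its tail region
was, cannot be recovered from the published description; the multiplicative
bonus with a 60-residue tail is a declared design decision, constrained
by the calibration anchor above.

## Parameters

| parameter | units | default | why |
|---|---|---|---|
| `peptide_length` (L) | residues | required | synthesis length; typical immunogens are 12–30 aa, worked examples use 15 and 18 |
| `epitope_length` (E) | residues | 7 | the contiguous stretch an antibody paratope typically engages in a linear epitope; drives uniqueness and conservation |
| `tail_length` (T) | residues | 60 | extent of the terminal regions treated as accessible tails |
| `tail_bonus` (B) | multiplier | 2 | weight of terminal accessibility against composition |
| `high_ig_threshold` | Ig units | 7 | the conventional high-immunogenicity band of this score |
| hydropathy display window | residues | 9 | the conventional width for Kyte–Doolittle plots; display only |

## Uniqueness and conservation

Both predictors run on exact, case-insensitive substring matching of
epitope-length k-mers — the mechanistic reading of "epitope matching"
with a user-set epitope length. No mismatches, no alignment.

* **Uniqueness** (specificity predictor): the fraction of a window's
  `L − E + 1` k-mers that occur in *no* off-target protein of the
  background proteome. Off-target excludes the target's own id, any
  proteome id sharing its accession root before a hyphen (the UniProt
  isoform convention `P12345-2`), and any ids the user passes explicitly;
  internal repeats within the target are self, never off-target.
* **Conservation** (cross-reactivity predictor): per species, the
  fraction of the window's k-mers present *anywhere* in that species'
  ortholog set — presence, not position, because a cross-reacting
  antibody only needs its epitope to exist in the ortholog. The overall
  score is the unweighted mean across species.

Fractions, rather than binary flags, were chosen because graded scores
reproduce "partially unique / partially conserved" situations and reduce
to the binary statements at 1.0 and 0.0. For prose output, scores
≥ 0.999 read as "unique"/"conserved", 0 as "none", anything between as
"partial". K-mers containing nonstandard letters (B, Z, X, U, O) are
never indexed and never counted as hits; windows containing them are
flagged (`has_nonstandard_epitope`) so a run on a degenerate sequence is
visible rather than silently optimistic.

## Feature overlay

Features use the UniProt controlled vocabulary and 1-based inclusive
coordinates throughout. Overlap is the inclusive interval test
`max(starts) <= min(ends)` — adjacency is not overlap. The kind-to-flag
mapping is: PTM = `MOD_RES`, `CARBOHYD`, `LIPID`, `DISULFID`; variant =
`VARIANT`; splice/conflict = `VAR_SEQ`, `CONFLICT`; membrane =
`TRANSMEM`; context (listed, never warned about) = `TOPO_DOM`, `DOMAIN`,
`SIGNAL` and unknown kinds. Including `DISULFID` among PTMs is a judgment
call: a disulfide bridge constrains and chemically modifies the epitope
much as glycosylation does. Flags are advisory — flagged windows stay in
the report so trade-offs can be judged — with opt-in exclusion switches
(`exclude_ptm`, `exclude_transmem`) for users who want hard filters. A
deliberate non-goal is folding feature penalties into the Ig-score:
immunogenicity and annotation tracks are kept separate, jointly viewed.

## Secondary-structure display track

The colored secondary-structure track is display-only. Full Chou–Fasman
nucleation/extension is out of scope; instead each residue gets the
5-wide centered means of `Pa`, `Pb`, `Pt` (truncated at the ends) and a
label by the classic former cutoffs, in priority order: `TURN_STRONG`
(mPt ≥ 1.10 and mPt ≥ max(mPa, mPb)), `TURN_WEAK` (1.00 ≤ mPt < 1.10,
same dominance), `HELIX` (mPa ≥ 1.06, mPa > mPb), `SHEET` (mPb ≥ 1.05,
mPb ≥ mPa), else `NONE`. This is a declared stand-in for whatever
procedure produced the original four-class display, not a claim about
it; nothing downstream consumes the labels.

## The synthetic-data generator

`simulate_proteome()`, `simulate_protein()` and `simulate_ortholog()`
exist so that every module — including file readers, via FASTA/TSV
round-trips — is testable with no downloads. They emulate: uniform-ish
random protein sequences with a controllable residue composition,
planted shared k-mers (off-target hits at known positions), planted
features, and orthologs derived by independent per-site substitution at
a set rate (rate 0 gives a perfectly conserved ortholog, rate 1 a fully
diverged one). The generator is deliberately naive about real evolution:
no indels, no phylogeny, no composition bias along the sequence, no
domain structure. Passing tests therefore demonstrate the *machinery* —
exact k-mer accounting, interval logic, ranking, determinism — on known
ground truth; they do not validate the biological effectiveness of any
scoring choice on real proteomes, which is what the accession-anchored
checks in `scripts/accession_check.R` probe.

Randomness is R's Mersenne-Twister with `sample.kind = "Rejection"`
under an explicit integer seed (via `withr::with_seed`, so the caller's
RNG stream is untouched); identical seeds give identical fixtures across
platforms.

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere; windows and features
  share the convention.
* Window means at sequence ends are truncated (mean over the residues
  actually available), for the display tracks; the Ig-score itself only
  ever averages over full windows.
* Component clamps make the score total on any input; degenerate inputs
  (single-residue proteins, windows equal to the whole protein,
  nonstandard letters) are handled, with nonstandard letters taking
  neutral scale defaults (KD 0, Pa = Pb = Pt = 1) so an X does not bias
  a window either way.
* Ranking ties share the minimum rank; file output is ordered by
  position with the rank as a column, so the TSV is byte-deterministic
  for identical inputs.
* Heat-map normalization metadata (per-track min/max) ships with the
  report; normalized columns are `(x − min)/(max − min)`, defined as 0
  for a constant track. `NA` (track not computed, e.g. no proteome
  supplied) is distinct from a computed 0 throughout.
* The TSV writer emits floats at 3 decimals and joins list cells with
  `;` (an empty set is an empty cell, not `NA`); the JSON writer is the
  full-precision, schema-versioned dump.

## Problem sizes

The test suite runs entirely on generated fixtures: proteomes of up to
20 proteins of 40–200 residues, windows of length 7–18, epitope lengths
3–7, and brute-force oracles (naive substring scans, all-pairs interval
checks, quadratic rank counts) at those sizes. These sizes exercise
every code path — boundary truncation, tail membership on both termini,
tied ranks, nonstandard letters — while keeping each oracle trivially
auditable. The index itself is a hash map from k-mer to id set and
handles proteome-scale FASTA inputs; build time grows linearly in total
residues.

## Known limitations

* Linear epitopes only: no 3-D structure, surface-probability or
  conformational-epitope modeling.
* Exact k-mer matching: a single conservative substitution in an
  ortholog breaks all k-mers crossing it, so conservation is a strict
  lower bound on practical cross-reactivity; BLAST-style fuzzy matching
  is a non-goal.
* The flat-text reader supports the modern qualifier-style FT dialect
  only, and the tool is release-agnostic about UniProt: results inherit
  whatever the supplied files contain.
* The secondary-structure track is a simplified display heuristic.
* PTM awareness is only as good as the supplied annotations; absence of
  a `MOD_RES` line is not evidence of absence of modification.
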