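# immunopep

Peptide-immunogen design for antibody production, offline and scriptable.

Most new antibodies are raised against synthetic peptides of roughly 12–30
residues. Choosing the peptide well means juggling several properties at
once: it should be **immunogenic** (hydrophilic, turn-prone, ideally in a
disordered terminal tail), **unique** in the background proteome (so the
antibody is specific), **conserved** in the other species you care about
(so the antibody cross-reacts), and clear of **PTM sites, sequence
variants, splice conflicts and transmembrane segments** that can ablate or
bury the epitope. `immunopep` computes all of these for *every* candidate
window of a target protein and emits one ranked, track-aligned table, so
the trade-offs can be judged side by side.

## The model

For a protein of length *n* and a chosen peptide length *L*, all
*n − L + 1* windows are scored with a composite immunogenicity score

```
Ig = 10 · H · T · B
H  = clamp((4.5 − meanKD) / 9, 0, 1)          hydrophilicity
T  = clamp((meanPt − 0.47) / 1.09, 0, 1)      turn propensity
B  = tail_bonus if the window lies entirely within
     tail_length residues of either terminus, else 1
```

where `meanKD` is the window's mean Kyte–Doolittle hydropathy (range
[−4.5, 4.5]) and `meanPt` its mean Chou–Fasman beta-turn parameter (range
[0.47, 1.56] over the 20 residues), so `H` and `T` each rescale their scale's
span to [0, 1]. Defaults: `tail_length` 60, `tail_bonus` 2; a score of 7
or more is treated as high immunogenicity. Windows get competition ranks
(ties share the best rank).

Specificity and cross-reactivity use exact epitope-length *k*-mer matching
(default *E* = 7): **uniqueness** is the fraction of a window's *E*-mers
found in no off-target protein of the background proteome (isoform
accessions of the target count as self), and **conservation** per species
is the fraction of its *E*-mers present anywhere in that species' ortholog
set. Feature overlap is an inclusive interval test against UniProt-style
features (`MOD_RES`, `CARBOHYD`, `TRANSMEM`, `VARIANT`, `VAR_SEQ`, ...).

## Worked example

Everything is testable offline via the deterministic fixture generator:

```r
library(immunopep)

target   <- simulate_protein(120, seed = 7, id = "DEMO1")
proteome <- dplyr::bind_rows(
  target,
  simulate_ortholog(target, 0.15, seed = 8, id = "PARA1"),  # paralog-like
  simulate_proteome(5, c(80, 200), seed = 9)
)
mouse <- simulate_ortholog(target, 0.05, seed = 10, id = "Demo1_mouse")

rep <- run_design(
  target, design_params(peptide_length = 18, epitope_length = 7),
  proteome = proteome, orthologs = list(mouse = mouse)
)
print(rep, n = 3)
```

```
peptide design report for DEMO1 (120 aa)
design parameters: L = 18 E = 7 T = 60 B = 2 high-Ig threshold = 7
103 candidate windows; top ranked:
# A tibble: 3 × 7
  start   end peptide     ig_score ig_rank uniqueness_score conservation_overall
  <int> <int> <chr>          <dbl>   <int>            <dbl>                <dbl>
1    81    98 YYQSHNNTGI…     7.14       1            0.583                0.5
2    82    99 YQSHNNTGIG…     7.00       2            0.583                0.583
3    83   100 QSHNNTGIGR…     6.76       3            0.583                0.583
```

The rank-1 window scores 7.14 (high immunogenicity, and it sits in the
C-terminal tail so the ×2 bonus applies), but only 58% of its 7-mers are
unique — the planted paralog `PARA1` shares the rest — and half are
conserved in the simulated mouse ortholog. `tidy(rep)` returns the full
per-window tibble, `glance(rep)` a one-row summary,
`ggplot2::autoplot(rep)` the aligned heat-map tracks, and
`write_report_tsv()` / `write_report_json()` the file outputs.

Real inputs come from `read_fasta()` or `read_uniprot_text()` (a UniProt
flat-text record, whose `FT` features feed the overlap flags directly),
with `read_feature_table()` as a plain-TSV fallback. A command-line
wrapper is installed at `system.file("cli/immunopep.R", package =
"immunopep")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/immunopep.R", package="immunopep"))')" \
  --target target.fasta --peptide-length 18 --epitope-length 7 \
  --proteome human.fasta --ortholog mouse=mouse.fa --ortholog rat=rat.fa \
  --out design --format both
```

`scripts/fetch_uniprot.R` (network) downloads UniProt records for use as
local inputs; `scripts/accession_check.R` then re-derives the published
design coordinates for the nephrin, podocin and ApoL1 antibodies from
those records.

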